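#' Read and validate a newick phylogeny
#'
#' Wraps [ape::read.tree()] with the checks the dispersion and UniFrac
#' stages rely on: unique tip labels and non-negative branch lengths.
#' Branch lengths are required by default because cophenetic distances are
#' meaningless without them.
#'
#' @param path newick file path.
#' @param assume_unit_branch_lengths if `TRUE`, a tree without branch
#'   lengths gets unit lengths instead of an error.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path, assume_unit_branch_lengths = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("could not parse newick in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("could not parse newick in ", path)
  validate_tree(tr, assume_unit_branch_lengths)
}

# shared validation for read and simulated trees
validate_tree <- function(tr, assume_unit_branch_lengths = FALSE) {
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    if (!assume_unit_branch_lengths)
      stop("tree has no branch lengths; ",
           "set assume_unit_branch_lengths = TRUE to use unit lengths")
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) stop("tree has missing branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}

# error (naming offenders) unless every table taxon is a tree tip
check_taxa_on_tree <- function(taxa, tree) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L))
  invisible(TRUE)
}
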