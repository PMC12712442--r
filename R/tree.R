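## Phylogeny handling: Newick I/O, grafting unplaced species into their genera,
## pruning to a trait table, Brownian covariance, Pagel's lambda transform.
## Trees are ape "phylo" objects; tip labels are canonical binomials with
## underscores (the Newick convention).

tip_species <- function(tree) canonical_species(tree$tip.label)

#' Read / write Newick trees
#'
#' Thin wrappers around ape's parser that additionally reject duplicate tip
#' labels (fatal for trait alignment).
#'
#' @param text a Newick string, or `file` a path.
#' @param file path to a Newick file.
#' @return `read_newick`: an `ape::phylo`; `write_newick`: the Newick string
#'   (invisibly when written to a file).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  tree
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' Graft missing species into their genus clades
#'
#' Species in the trait table but absent from the tree are attached at a
#' random position inside the clade of congeneric tips: a random edge of the
#' genus clade (uniform by edge count), then a uniform point along it; on an
#' ultrametric tree the new terminal branch is extended so tip depths are
#' preserved. Deterministic given `seed`. Species whose genus has no tip are
#' skipped with a warning.
#'
#' @param tree `ape::phylo` with binomial tip labels.
#' @param species character vector of binomials to add.
#' @param seed integer RNG seed.
#' @return list with `tree` (augmented) and `skipped` (character vector).
#' @export
graft_species_to_genus <- function(tree, species, seed) {
  stopifnot(inherits(tree, "phylo"))
  species <- canonical_species(species)
  set.seed(as.integer(seed))
  skipped <- character()
  for (sp in species) {
    gen <- species_genus(sp)
    hit <- which(species_genus(tip_species(tree)) == gen)
    if (length(hit) == 0L) { skipped <- c(skipped, sp); next }
    new_label <- gsub(" ", "_", sp)
    if (new_label %in% tree$tip.label) next # already present
    if (length(hit) == 1L) {
      # single congener: attach along its terminal edge
      edge_rows <- which(tree$edge[, 2] == hit)
    } else {
      mrca <- ape::getMRCA(tree, hit)
      clade_nodes <- c(phangorn_descendants(tree, mrca), mrca)
      edge_rows <- which(tree$edge[, 1] %in% clade_nodes &
                           tree$edge[, 2] %in% setdiff(clade_nodes, mrca))
    }
    row <- if (length(edge_rows) == 1L) edge_rows else sample(edge_rows, 1L)
    child <- tree$edge[row, 2]
    len <- tree$edge.length[row]
    pos <- stats::runif(1, 0, len) # distance below the child node
    tree <- phytools::bind.tip(tree, tip.label = new_label,
                               edge.length = NULL, where = child,
                               position = pos)
  }
  if (length(skipped))
    warning("no congeneric tips for: ", paste(skipped, collapse = ", "))
  list(tree = tree, skipped = skipped)
}

## all descendant node/tip indices of `node` (excluding it), iterative
phangorn_descendants <- function(tree, node) {
  out <- integer(); stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- kids[[as.character(nd)]]
    if (!is.null(ch)) { out <- c(out, ch); stack <- c(stack, ch) }
  }
  out
}

#' Prune a tree to the species present in a trait table
#'
#' Keeps the intersection of tree tips and table species, suppressing
#' degree-two nodes (branch lengths are summed, so pairwise path distances
#' among retained tips are preserved).
#'
#' @param tree `ape::phylo`.
#' @param species character vector (or data.frame with a `species` column).
#' @return list with `tree` (pruned) and `species` (canonical binomials in
#'   tip order).
#' @export
prune_to_overlap <- function(tree, species) {
  if (is.data.frame(species)) species <- species$species
  species <- canonical_species(species)
  keep <- tree$tip.label[tip_species(tree) %in% species]
  if (length(keep) == 0L) stop("no overlap between tree tips and species table")
  pruned <- ape::keep.tip(tree, keep)
  list(tree = pruned, species = tip_species(pruned))
}

#' Brownian phylogenetic covariance matrix
#'
#' C\[i, j\] is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths. Under Brownian motion the expected trait
#' covariance is proportional to C.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @return numeric matrix with canonical species row/col names.
#' @export
phylo_vcv <- function(tree) {
  C <- ape::vcv.phylo(tree)
  dimnames(C) <- list(canonical_species(rownames(C)), canonical_species(colnames(C)))
  C
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`, leaving tip depths unchanged:
#' lambda = 1 is Brownian motion, lambda = 0 removes all phylogenetic
#' covariance.
#'
#' @param C covariance matrix from [phylo_vcv()].
#' @param lambda value in \[0, 1\].
#' @return transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1 + 1e-8)
    stop("lambda must be a single value in [0, 1]")
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

## Cholesky solve with diagonal jitter fallback
chol_safe <- function(C) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-10 * mean(diag(C))
    ch <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
    if (is.null(ch)) stop("covariance matrix is singular; consider jittering branch lengths")
  }
  ch
}

#' Phylogenetically weighted (GLS) mean
#'
#' The generalized-least-squares estimate of the root state under Brownian
#' motion: (1' C^-1 1)^-1 1' C^-1 x. Equals the arithmetic mean on a star
#' phylogeny.
#'
#' @param x named or tree-ordered trait vector.
#' @param C covariance from [phylo_vcv()] (same order as `x`).
#' @return scalar estimate in trait units.
#' @export
phylo_weighted_mean <- function(x, C) {
  stopifnot(length(x) == nrow(C))
  ch <- chol_safe(C)
  w <- backsolve(ch, forwardsolve(t(ch), rep(1, nrow(C))))
  sum(w * x) / sum(w)
}
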