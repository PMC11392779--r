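#' Read and validate a newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contracts the
#' branch-length engine relies on: a single rooted tree, unique leaf
#' labels, and a branch length on every edge.
#'
#' @param text Newick string, or `NULL` to read from `file`.
#' @param file Path to a newick file (alternative to `text`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(file = file) else ape::read.tree(text = text),
    error = function(e) {
      abort(paste0("Failed to parse newick: ", conditionMessage(e)),
            class = "divscape_parse_error")
    }
  )
  if (is.null(tree)) {
    abort("Failed to parse newick: no tree found in input.",
          class = "divscape_parse_error")
  }
  validate_tree(tree)
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    abort("Expected a `phylo` tree.", class = "divscape_parse_error")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate leaf label(s): ", paste(dup, collapse = ", ")),
          class = "divscape_parse_error")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("Every edge must carry a branch length.",
          class = "divscape_parse_error")
  }
  if (any(tree$edge.length < 0)) {
    abort("Branch lengths must be non-negative.",
          class = "divscape_parse_error")
  }
  invisible(tree)
}

# Edges x leaves incidence: M[e, s] is TRUE iff leaf s descends from the
# child end of edge e. Computed by one postorder sweep.
edge_leaf_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  M <- matrix(FALSE, n_node, n_tip, dimnames = list(NULL, tree$tip.label))
  M[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    M[p, ] <- M[p, ] | M[ch, ]
  }
  M[tree$edge[, 2], , drop = FALSE]
}

match_leaves <- function(tree, labels) {
  idx <- match(labels, tree$tip.label)
  if (anyNA(idx)) {
    abort(paste0("Species not found among tree leaves: ",
                 paste(labels[is.na(idx)], collapse = ", ")),
          class = "divscape_lookup_error")
  }
  idx
}

#' Branch-length diversity of a leaf set (Faith-style)
#'
#' Sums the branch lengths of the subtree spanning `leafset`. With
#' `mode = "mrca"` the subtree is rooted at the set's most recent common
#' ancestor (a singleton therefore scores 0); with `mode = "root"` the
#' path from the MRCA up to the tree root is included as well, the
#' classical Faith convention.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param leafset Character vector of leaf labels (at least one).
#' @param mode `"root"` (default) or `"mrca"`.
#' @return Total branch length (numeric scalar).
#' @export
branch_sum_diversity <- function(tree, leafset, mode = c("root", "mrca")) {
  mode <- match.arg(mode)
  validate_tree(tree)
  stopifnot(length(leafset) >= 1)
  idx <- match_leaves(tree, leafset)
  M <- edge_leaf_incidence(tree)
  inset <- M[, idx, drop = FALSE]
  present <- rowSums(inset) > 0
  if (mode == "mrca") {
    # edges whose descendant set contains the whole leafset lie on the
    # root-to-MRCA path and are excluded
    present <- present & rowSums(inset) < length(idx)
  }
  sum(tree$edge.length[present])
}

#' Per-cell range-weighted endemism from a branch-length tree
#'
#' For each grid cell, sums `L_b / |r_b|` over the branches `b` of the
#' subtree spanning the cell's species (same `mode` convention as
#' [branch_sum_diversity()]), where `|r_b|` is the branch range: the
#' number of cells containing at least one descendant of `b`. Applied to
#' a phylogeny this is phylogenetic endemism (PE); applied to a
#' functional dendrogram it is functional endemism (FE). The branch table
#' (lengths, descendant sets, ranges) is built once and reused across
#' cells.
#'
#' @param tree A `phylo` tree with branch lengths covering all occurring
#'   species.
#' @param presence A `presence_matrix`.
#' @param mode `"root"` (default) or `"mrca"`.
#' @param normalize_by_area If `TRUE`, branch ranges are expressed as a
#'   fraction of the number of occupied cells rather than a cell count
#'   (rescales all values by the occupied-cell total). Off by default.
#' @return Numeric vector of per-cell endemism, one entry per grid cell
#'   (row-major); `NA` for empty cells.
#' @export
range_weighted_endemism <- function(tree, presence,
                                    mode = c("root", "mrca"),
                                    normalize_by_area = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(presence, "presence_matrix"))
  validate_tree(tree)
  missing <- setdiff(presence$species, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("Species missing from the tree: ",
                 paste(missing, collapse = ", ")),
          class = "divscape_lookup_error")
  }
  M <- edge_leaf_incidence(tree)[, presence$species, drop = FALSE]
  P <- presence$presence  # cells x species
  counts <- M %*% t(P)    # edges x cells: occurring descendants per cell
  inter <- counts > 0
  range_b <- rowSums(inter)  # branch range in cells
  if (normalize_by_area) range_b <- range_b / sum(rowSums(P) > 0)
  w <- ifelse(range_b > 0, tree$edge.length / range_b, 0)
  richness <- rowSums(P)
  if (mode == "mrca") {
    superset <- counts >= rep(richness, each = nrow(counts))
    use <- inter & !superset
  } else {
    use <- inter
  }
  val <- as.numeric(t(use) %*% w)
  val[richness == 0] <- NA_real_
  val
}

#' Per-cell branch-length diversity surface
#'
#' Vectorised [branch_sum_diversity()] over every occupied cell of a
#' presence matrix.
#'
#' @inheritParams range_weighted_endemism
#' @return Numeric vector of per-cell diversity (row-major); `NA` for
#'   empty cells.
#' @export
branch_diversity_surface <- function(tree, presence, mode = c("root", "mrca")) {
  mode <- match.arg(mode)
  stopifnot(inherits(presence, "presence_matrix"))
  validate_tree(tree)
  missing <- setdiff(presence$species, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("Species missing from the tree: ",
                 paste(missing, collapse = ", ")),
          class = "divscape_lookup_error")
  }
  M <- edge_leaf_incidence(tree)[, presence$species, drop = FALSE]
  P <- presence$presence
  counts <- M %*% t(P)
  inter <- counts > 0
  richness <- rowSums(P)
  if (mode == "mrca") {
    superset <- counts >= rep(richness, each = nrow(counts))
    use <- inter & !superset
  } else {
    use <- inter
  }
  val <- as.numeric(t(use) %*% tree$edge.length)
  val[richness == 0] <- NA_real_
  val
}

node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Graft species missing from the tree onto their genus
#'
#' Species present in the occurrence data but absent from the phylogeny
#' are attached at genus level. A species whose genus has two or more
#' leaves in the tree is added as a new child of the genus MRCA (creating
#' a polytomy) with pendant length equal to the mean depth of the MRCA's
#' existing leaves below it; a species whose genus has exactly one leaf is
#' attached at the midpoint of that leaf's pendant branch. Species whose
#' genus has no leaf in the tree are dropped and logged. An ultrametric
#' input tree remains ultrametric.
#'
#' @param tree A `phylo` tree.
#' @param new_species Data frame with `species`, `genus`: the species to
#'   graft.
#' @param leaf_genus Data frame with `species`, `genus` mapping existing
#'   leaf labels to genera. Defaults to the leaf-label prefix before the
#'   first underscore.
#' @return List with `tree` (augmented) and `log` (tibble: `species`,
#'   `genus`, `action`, `attachment_depth`).
#' @export
graft_missing_species <- function(tree, new_species, leaf_genus = NULL) {
  validate_tree(tree)
  ns <- tibble::as_tibble(new_species)
  stopifnot(all(c("species", "genus") %in% names(ns)))
  if (is.null(leaf_genus)) {
    leaf_genus <- tibble::tibble(
      species = tree$tip.label,
      genus = sub("_.*$", "", tree$tip.label)
    )
  }
  genus_of <- setNames(as.character(leaf_genus$genus),
                       as.character(leaf_genus$species))
  log <- list()
  for (i in seq_len(nrow(ns))) {
    sp <- as.character(ns$species[i]); gen <- as.character(ns$genus[i])
    members <- tree$tip.label[genus_of[tree$tip.label] == gen &
                                !is.na(genus_of[tree$tip.label])]
    if (length(members) == 0) {
      log[[length(log) + 1]] <- tibble::tibble(
        species = sp, genus = gen, action = "dropped",
        attachment_depth = NA_real_)
      next
    }
    depths <- node_depths(tree)
    n_tip <- length(tree$tip.label)
    if (length(members) >= 2) {
      node <- ape::getMRCA(tree, members)
      clade_tips <- ape::extract.clade(tree, node)$tip.label
      pend <- mean(depths[match(clade_tips, tree$tip.label)]) - depths[node]
      tree <- phytools::bind.tip(tree, sp, edge.length = pend,
                                 where = node, position = 0)
      attach_depth <- depths[node]
    } else {
      leaf <- match(members, tree$tip.label)
      pend_edge <- which(tree$edge[, 2] == leaf)
      half <- tree$edge.length[pend_edge] / 2
      tree <- phytools::bind.tip(tree, sp, edge.length = half,
                                 where = leaf, position = half)
      attach_depth <- depths[leaf] - half
    }
    genus_of[sp] <- gen
    log[[length(log) + 1]] <- tibble::tibble(
      species = sp, genus = gen, action = "grafted",
      attachment_depth = attach_depth)
  }
  list(
    tree = tree,
    log = if (length(log)) dplyr::bind_rows(log) else
      tibble::tibble(species = character(), genus = character(),
                     action = character(), attachment_depth = numeric())
  )
}
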