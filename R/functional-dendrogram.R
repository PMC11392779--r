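#' Declare trait types and weights
#'
#' @param trait Trait (column) names.
#' @param type One of `"binary"`, `"ordinal"`, `"continuous"`,
#'   `"categorical"` per trait (recycled).
#' @param weight Per-trait weight in `[0, 1]` (recycled); in the drought
#'   application, higher weight marks traits more important for drought
#'   resistance.
#' @return Tibble with `trait`, `type`, `weight`.
#' @export
trait_meta <- function(trait, type, weight = 1) {
  type <- rep_len(type, length(trait))
  weight <- rep_len(weight, length(trait))
  bad <- setdiff(type, c("binary", "ordinal", "continuous", "categorical"))
  if (length(bad) > 0) {
    abort(paste0("Unknown trait type(s): ", paste(bad, collapse = ", ")),
          class = "divscape_invalid_config")
  }
  if (any(weight < 0 | weight > 1)) {
    abort("Trait weights must lie in [0, 1].",
          class = "divscape_invalid_config")
  }
  if (all(weight == 0)) {
    abort("Trait weights must not all be zero.",
          class = "divscape_invalid_config")
  }
  tibble::tibble(trait = trait, type = type, weight = weight)
}

#' Weighted Gower similarity for mixed-type traits
#'
#' Computes `S_ij = sum_k w_k d_ijk s_ijk / sum_k w_k d_ijk`, where
#' `d_ijk` is 1 iff trait `k` is non-missing for both species, and the
#' per-trait similarity `s_ijk` is an exact match indicator for binary and
#' categorical traits, `1 - |x_ik - x_jk| / range_k` for continuous
#' traits, and the same on tie-averaged ranks rescaled to the observed
#' rank range for ordinal traits. Trait ranges are taken over the full
#' species pool. A species pair sharing no positively weighted observed
#' trait is an error (no silent imputation).
#'
#' @param traits Data frame: `species` column plus one column per trait.
#'   Missing values allowed (`NA`).
#' @param meta Trait metadata from [trait_meta()]; defaults to all traits
#'   continuous with weight 1.
#' @return Symmetric species x species similarity matrix with unit
#'   diagonal.
#' @export
weighted_gower_similarity <- function(traits, meta = NULL) {
  tr <- tibble::as_tibble(traits)
  stopifnot("species" %in% names(tr))
  species <- as.character(tr$species)
  if (anyDuplicated(species)) {
    abort("Duplicate species in trait table.",
          class = "divscape_invalid_input")
  }
  cols <- setdiff(names(tr), "species")
  if (is.null(meta)) meta <- trait_meta(cols, "continuous", 1)
  meta <- tibble::as_tibble(meta)
  if (!setequal(meta$trait, cols)) {
    abort("Trait metadata must cover exactly the trait columns.",
          class = "divscape_invalid_config")
  }
  n <- length(species)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (k in seq_len(nrow(meta))) {
    w <- meta$weight[k]
    if (w == 0) next
    x <- tr[[meta$trait[k]]]
    obs <- !is.na(x)
    dd <- tcrossprod(obs)  # d_ijk
    s <- matrix(0, n, n)
    if (meta$type[k] %in% c("binary", "categorical")) {
      xx <- as.character(x)
      s[dd > 0] <- outer(xx, xx, "==")[dd > 0]
    } else {
      v <- as.numeric(x)
      if (meta$type[k] == "ordinal") {
        v[obs] <- rank(v[obs], ties.method = "average")
      }
      rng <- diff(range(v, na.rm = TRUE))
      d <- abs(outer(v, v, "-"))
      s <- if (rng > 0) 1 - d / rng else matrix(1, n, n)
      s[dd == 0] <- 0
    }
    num <- num + w * s * dd
    den <- den + w * dd
  }
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad) > 0) {
      pair <- paste0(species[bad[1, 1]], " / ", species[bad[1, 2]])
      abort(paste0("Species pair with no shared weighted trait: ", pair),
            class = "divscape_incomparable_pair")
    }
  }
  S <- num / den
  dimnames(S) <- list(species, species)
  diag(S) <- 1
  S
}

#' Gower dissimilarity matrix (D = 1 - S)
#'
#' @inheritParams weighted_gower_similarity
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
weighted_gower_dissimilarity <- function(traits, meta = NULL) {
  1 - weighted_gower_similarity(traits, meta)
}

validate_dissimilarity <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort("Dissimilarity must be a square matrix.",
          class = "divscape_invalid_input")
  }
  if (any(D < 0)) {
    abort("Dissimilarity values must be non-negative.",
          class = "divscape_invalid_input")
  }
  if (max(abs(D - t(D))) > 1e-12) {
    abort("Dissimilarity matrix must be symmetric.",
          class = "divscape_invalid_input")
  }
  invisible(D)
}

#' UPGMA dendrogram from a dissimilarity matrix
#'
#' Unweighted pair-group average-linkage agglomeration. At each step the
#' pair of clusters with the smallest average dissimilarity is merged at a
#' node of height equal to half that dissimilarity, so leaf depths are all
#' equal (the dendrogram is ultrametric). Exact ties are broken by the
#' lexicographically smallest pair of cluster representatives (a cluster's
#' representative is its smallest member label), making the topology
#' reproducible across platforms.
#'
#' @param D Square symmetric dissimilarity matrix with species labels as
#'   dimnames.
#' @return An ultrametric `phylo` dendrogram.
#' @export
upgma <- function(D) {
  validate_dissimilarity(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2) {
    abort("UPGMA needs at least two species.",
          class = "divscape_invalid_input")
  }
  d <- D
  dimnames(d) <- NULL
  active <- seq_len(n)
  size <- rep(1L, n)
  rep_lab <- labels
  newick <- labels
  height <- rep(0, n)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    sub <- d[active, active, drop = FALSE]
    sub[!upper.tri(sub)] <- Inf
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      # lexicographic tie-break on sorted representative labels
      key <- apply(cand, 1, function(rc) {
        reps <- sort(c(rep_lab[active[rc[1]]], rep_lab[active[rc[2]]]))
        paste(reps, collapse = "\r")
      })
      cand <- cand[order(key)[1], , drop = FALSE]
    }
    i <- active[cand[1, 1]]; j <- active[cand[1, 2]]
    h <- dmin / 2
    nw <- sprintf("(%s:%.12g,%s:%.12g)",
                  newick[i], h - height[i], newick[j], h - height[j])
    # average-linkage update into slot i
    others <- setdiff(active, c(i, j))
    d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
      (size[i] + size[j])
    d[others, i] <- d[i, others]
    size[i] <- size[i] + size[j]
    newick[i] <- nw
    height[i] <- h
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active <- setdiff(active, j)
  }
  read_newick(paste0(newick[active], ";"))
}

#' Functional diversity and endemism surfaces
#'
#' FD is [branch_sum_diversity()] and FE is [range_weighted_endemism()]
#' evaluated on the functional dendrogram instead of the phylogeny.
#'
#' @param dendrogram Functional dendrogram (`phylo`), leaves covering all
#'   occurring species.
#' @param presence A `presence_matrix`.
#' @param mode `"root"` (default) or `"mrca"`, as in
#'   [branch_sum_diversity()].
#' @return Tibble with `row`, `col`, `fd`, `fe` for occupied cells.
#' @export
fd_fe_surfaces <- function(dendrogram, presence, mode = c("root", "mrca")) {
  mode <- match.arg(mode)
  fd <- branch_diversity_surface(dendrogram, presence, mode)
  fe <- range_weighted_endemism(dendrogram, presence, mode)
  occ <- which(rowSums(presence$presence) > 0)
  cell <- occ - 1L
  tibble::tibble(
    row = cell %/% presence$grid$n_cols,
    col = cell %% presence$grid$n_cols,
    fd = fd[occ], fe = fe[occ]
  )
}
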