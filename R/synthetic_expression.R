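# Synthetic expression stand-in for the bulk RNA-seq comparison: multi-state
# mixtures over three gene groups (cancer/P53, EMT/ZEB, stemness/OCT4),
# reduced to three coordinates by group-wise PCA, clustered, and matched to
# landscape attractor positions.

#' Default gene-group map: 40 genes, 18 cancer / 11 EMT / 11 stemness
#' @return data.frame(gene, group) with groups "P53", "ZEB", "OCT4".
#' @export
default_gene_groups <- function() {
  data.frame(
    gene = c(sprintf("CANC%02d", 1:18), sprintf("EMT%02d", 1:11),
             sprintf("STEM%02d", 1:11)),
    group = rep(c("P53", "ZEB", "OCT4"), c(18, 11, 11)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-state expression matrix
#'
#' Each sample belongs to a latent state with a 3-coordinate mean (one
#' coordinate per gene group); gene values are the state coordinate times a
#' positive gene loading plus Gaussian noise, truncated at zero. This
#' emulates the structure the landscape comparison needs — downstream genes
#' whose transcription reflects the group's driver activity — and nothing
#' else about real tumor RNA-seq (no counts, library sizes or batches).
#'
#' @param centers numeric matrix, states x 3 columns named by group
#'   (P53, ZEB, OCT4); rownames are state labels.
#' @param n_per_state samples per state (scalar or per-state vector, >= 2).
#' @param noise Gaussian noise standard deviation on each gene.
#' @param seed integer seed.
#' @param gene_groups gene-group map (default [default_gene_groups()]).
#' @param loadings optional named list of per-group positive loading vectors;
#'   default: evenly spaced in [0.6, 1.4].
#' @return An `expression_matrix`: `X` (samples x genes), `gene_groups`,
#'   `state` (ground-truth labels), `centers`, `seed`.
#' @export
generate_expression <- function(centers, n_per_state = 50, noise = 0.5,
                                seed = 1, gene_groups = default_gene_groups(),
                                loadings = NULL) {
  stopifnot(ncol(centers) == 3, nrow(centers) >= 2, all(n_per_state >= 2))
  if (is.null(rownames(centers))) rownames(centers) <- paste0("state", seq_len(nrow(centers)))
  if (anyDuplicated(as.data.frame(centers)) > 0) stop("state centers must be distinct")
  groups <- unique(gene_groups$group)
  stopifnot(length(groups) == 3, all(colnames(centers) %in% groups))
  n_per_state <- rep_len(n_per_state, nrow(centers))
  if (is.null(loadings)) {
    loadings <- lapply(groups, function(g) {
      ng <- sum(gene_groups$group == g)
      seq(0.6, 1.4, length.out = ng)
    })
    names(loadings) <- groups
  }
  set.seed(as.integer(seed))
  rows <- list(); labels <- character(0)
  for (s in seq_len(nrow(centers))) {
    for (i in seq_len(n_per_state[s])) {
      x <- numeric(nrow(gene_groups))
      for (g in groups) {
        gi <- which(gene_groups$group == g)
        x[gi] <- centers[s, g] * loadings[[g]]
      }
      x <- x + rnorm(length(x), sd = noise)
      rows[[length(rows) + 1]] <- pmax(x, 0)
      labels <- c(labels, rownames(centers)[s])
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- gene_groups$gene
  rownames(X) <- sprintf("S%04d", seq_len(nrow(X)))
  structure(list(X = X, gene_groups = gene_groups, state = labels,
                 centers = centers, seed = as.integer(seed)),
            class = "expression_matrix")
}

#' Group-wise PCA embedding to three coordinates
#'
#' Takes the leading principal component of each gene group's submatrix; the
#' sign is fixed so every PC correlates positively with the group's mean
#' expression, making the embedding deterministic.
#'
#' @param expr an `expression_matrix` or plain samples x genes matrix.
#' @param gene_groups required if `expr` is a plain matrix.
#' @return samples x 3 matrix (columns = groups) of PC1 scores, with
#'   attribute `explained` (per-group PC1 variance fraction).
#' @export
groupwise_pca <- function(expr, gene_groups = NULL) {
  if (inherits(expr, "expression_matrix")) {
    gene_groups <- expr$gene_groups
    X <- expr$X
  } else X <- expr
  stopifnot(!is.null(gene_groups), nrow(X) >= 3)
  groups <- unique(gene_groups$group)
  emb <- matrix(NA_real_, nrow(X), length(groups),
                dimnames = list(rownames(X), groups))
  explained <- setNames(numeric(length(groups)), groups)
  for (g in groups) {
    sub <- X[, gene_groups$gene[gene_groups$group == g], drop = FALSE]
    stopifnot(ncol(sub) >= 2)
    if (all(apply(sub, 2, var) < .Machine$double.eps))
      stop(sprintf("group %s has zero variance", g))
    pc <- prcomp(sub, center = TRUE, scale. = FALSE)
    sc <- pc$x[, 1]
    mu <- rowMeans(sub)
    if (sd(mu) > 0 && cor(sc, mu) < 0) sc <- -sc
    emb[, g] <- sc
    explained[g] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  attr(emb, "explained") <- explained
  emb
}

#' Cluster an embedding with silhouette-selected k-means
#'
#' @param emb samples x d matrix.
#' @param k_range candidate cluster counts (default 2..8).
#' @param seed k-means seed.
#' @return list(cluster assignments, centers, k, silhouette profile).
#' @export
cluster_embedding <- function(emb, k_range = 2:8, seed = 1) {
  k_range <- k_range[k_range < nrow(emb)]
  sil <- setNames(numeric(length(k_range)), k_range)
  fits <- list()
  for (i in seq_along(k_range)) {
    set.seed(as.integer(seed))
    fit <- kmeans(emb, centers = k_range[i], nstart = 10, iter.max = 50)
    sw <- cluster::silhouette(fit$cluster, stats::dist(emb))
    sil[i] <- mean(sw[, "sil_width"])
    fits[[i]] <- fit
  }
  best <- which.max(sil)
  list(cluster = fits[[best]]$cluster, centers = fits[[best]]$centers,
       k = k_range[best], silhouette = sil)
}

#' Adjusted Rand index between two labelings
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Match expression clusters to landscape basins
#'
#' Standardizes cluster centers and basin minima per axis (z-scores over the
#' pooled set) and assigns each cluster to its nearest basin center; a basin
#' may be claimed by at most one cluster (greedy by distance).
#'
#' @param emb samples x 3 embedding (columns named by group = axis pairing).
#' @param basins labeled `basin_set` (or data.frame with label + axis columns).
#' @param clusters optional result of [cluster_embedding()]; computed if NULL.
#' @param axis_map named character vector mapping embedding columns to basin
#'   axes (default identity on shared names: P53, ZEB, OCT4).
#' @return list(matches data.frame(cluster, label, distance), n_clusters,
#'   unmatched clusters, clustering).
#' @export
compare_to_landscape <- function(emb, basins, clusters = NULL,
                                 axis_map = NULL) {
  sm <- if (inherits(basins, "basin_set")) basins$summary else basins
  if (is.null(axis_map)) {
    shared <- intersect(colnames(emb), colnames(sm))
    stopifnot(length(shared) >= 2)
    axis_map <- setNames(shared, shared)
  }
  if (is.null(clusters)) clusters <- cluster_embedding(emb)
  cc <- clusters$centers[, names(axis_map), drop = FALSE]
  bc <- as.matrix(sm[, axis_map, drop = FALSE])
  # standardize each set on its own per-axis scale: embedding scores are
  # centered PCA coordinates while basin minima are absolute copy numbers
  zscore <- function(m) {
    for (j in seq_len(ncol(m))) {
      sg <- sd(m[, j]); if (!is.finite(sg) || sg == 0) sg <- 1
      m[, j] <- (m[, j] - mean(m[, j])) / sg
    }
    m
  }
  cc <- zscore(cc); bc <- zscore(bc)
  D <- as.matrix(stats::dist(rbind(cc, bc)))[seq_len(nrow(cc)),
                                             nrow(cc) + seq_len(nrow(bc)),
                                             drop = FALSE]
  labels <- if (!is.null(sm$label)) sm$label else as.character(seq_len(nrow(bc)))
  matches <- data.frame(cluster = integer(0), label = character(0),
                        distance = numeric(0))
  Dw <- D
  repeat {
    if (all(!is.finite(Dw))) break
    ij <- which(Dw == min(Dw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    matches <- rbind(matches, data.frame(cluster = ij[1], label = labels[ij[2]],
                                         distance = D[ij[1], ij[2]]))
    Dw[ij[1], ] <- Inf
    Dw[, ij[2]] <- Inf
  }
  matches <- matches[order(matches$cluster), ]
  rownames(matches) <- NULL
  list(matches = matches, n_clusters = nrow(cc),
       unmatched = setdiff(seq_len(nrow(cc)), matches$cluster),
       clustering = clusters)
}
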