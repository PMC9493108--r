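## Conformational-space analysis: Mahalanobis outlier filtering of the
## per-image amplitude vectors, PCA embedding, declarative group
## selection (boxes or PC1 bins), and reference-model animation along
## principal axes.

#' Filter outlier amplitude estimates by Mahalanobis distance
#'
#' Distance of each amplitude vector from the sample mean under the
#' classical sample covariance; rows with distance above the threshold
#' are removed.  The reference protocol uses threshold 3.2.
#'
#' @param records A [particle_records()] table (K > M rows).
#' @param threshold Distance threshold (> 0).
#' @param ridge Diagonal regularization added to the covariance when
#'   it is numerically singular (default 0; try `1e-6`).
#' @return The kept records, with attributes `removed` (count) and
#'   `distances` (all K distances).
#' @export
mahalanobis_filter <- function(records, threshold = 3.2, ridge = 0) {
  if (threshold <= 0) stop("threshold must be > 0")
  amp <- records_amplitudes(records)
  if (nrow(amp) <= ncol(amp))
    stop("need more records than modes for an invertible covariance")
  cv <- stats::cov(amp) + diag(ridge, ncol(amp))
  ok <- tryCatch({solve(cv); TRUE}, error = function(e) FALSE)
  if (!ok)
    stop("singular amplitude covariance; rerun with ridge > 0 (e.g. 1e-6)")
  d <- sqrt(stats::mahalanobis(amp, colMeans(amp), cv))
  keep <- d <= threshold
  out <- records[keep, , drop = FALSE]
  class(out) <- c("particle_records", "data.frame")
  attr(out, "removed") <- sum(!keep)
  attr(out, "distances") <- d
  out
}

#' Fit a PCA conformational space
#'
#' Mean-centered PCA (singular value decomposition) of the per-image
#' normal-mode amplitude vectors.  Component signs are fixed
#' deterministically: the largest-magnitude loading of each component
#' is made positive.
#'
#' @param records A [particle_records()] table, or a plain K x M
#'   amplitude matrix.
#' @param d Embedding dimension (<= M; default 2).
#' @return An object of class `conformational_space`: `embedding`
#'   (K x d scores), `components` (d x M loadings), `mean`,
#'   `explained_variance` (non-increasing), `provenance`.
#' @export
pca_fit <- function(records, d = 2L) {
  amp <- if (is.matrix(records)) records else records_amplitudes(records)
  prov <- if (is.matrix(records)) rep("ground_truth", nrow(amp))
  else records$provenance
  m <- ncol(amp)
  if (d > m) stop(sprintf("d = %d exceeds the %d modes", d, m))
  pc <- stats::prcomp(amp, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  flip <- vapply(seq_len(d), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(amp, 2, pc$center) %*% rot
  structure(list(embedding = scores, components = t(rot),
                 mean = pc$center,
                 explained_variance = (pc$sdev^2)[seq_len(d)],
                 provenance = prov),
            class = "conformational_space")
}

#' @export
print.conformational_space <- function(x, ...) {
  tot <- sum(x$explained_variance)
  cat(sprintf("conformational_space: %d points, %d components\n",
              nrow(x$embedding), nrow(x$components)))
  cat("explained variance:",
      format(x$explained_variance, digits = 4), "\n")
  invisible(x)
}

#' Project amplitude vectors into an existing space
#'
#' @param space A `conformational_space`.
#' @param amplitudes K x M matrix (or [particle_records()]).
#' @return K x d score matrix.
#' @export
pca_project <- function(space, amplitudes) {
  amp <- if (is.matrix(amplitudes)) amplitudes
  else records_amplitudes(amplitudes)
  sweep(amp, 2, space$mean) %*% t(space$components)
}

#' Reconstruct amplitudes from embedding scores
#'
#' @param space A `conformational_space`.
#' @param scores K x d score matrix (or vector for one point).
#' @return K x M amplitude matrix.
#' @export
pca_backproject <- function(space, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  sweep(scores %*% space$components, 2, space$mean, "+")
}

#' Merge two record sets into one conformational space
#'
#' A single PCA over the union of the amplitude vectors; per-point
#' provenance is retained so mixed spaces (inferred + alignment
#' estimates) can be plotted and reported by source.
#'
#' @param records_a,records_b [particle_records()] tables with the
#'   same number of amplitude columns.
#' @param d Embedding dimension.
#' @return A `conformational_space`.
#' @export
merge_spaces <- function(records_a, records_b, d = 2L) {
  qa <- records_amplitudes(records_a)
  qb <- records_amplitudes(records_b)
  if (ncol(qa) != ncol(qb))
    stop("amplitude dimensions differ between record sets")
  space <- pca_fit(rbind(qa, qb), d)
  space$provenance <- c(as.character(records_a$provenance),
                        as.character(records_b$provenance))
  space
}

#' Select groups of images in a conformational space
#'
#' Declarative replacement for interactive region picking.  Two modes:
#' `regions` as a list of axis-aligned boxes (each a 2 x d matrix of
#' lower/upper bounds, or a length-2d vector `c(lo1, hi1, lo2, hi2)`),
#' or `pc1_bins` splitting an interval of the first principal
#' coordinate into equal-count bins after discarding tail fractions.
#' Groups smaller than `min_group_size` are dropped with a warning.
#'
#' @param space A `conformational_space`.
#' @param regions List of boxes (box mode).
#' @param pc1_bins Number of bins (bin mode).
#' @param tail_fraction Fraction of extreme-PC1 points excluded on
#'   each side in bin mode (default 0.05).
#' @param min_group_size Minimum points per group.
#' @return An object of class `group_selection`: `assignments`
#'   (integer per point, NA = unassigned), `groups` (list of index
#'   vectors), `mode`.
#' @export
select_groups <- function(space, regions = NULL, pc1_bins = NULL,
                          tail_fraction = 0.05, min_group_size = 1L) {
  emb <- space$embedding
  k <- nrow(emb)
  assign <- rep(NA_integer_, k)
  if (!is.null(regions)) {
    for (g in seq_along(regions)) {
      box <- regions[[g]]
      if (is.null(dim(box))) box <- matrix(box, nrow = 2)
      inside <- rep(TRUE, k)
      for (j in seq_len(ncol(box)))
        inside <- inside & emb[, j] >= box[1, j] & emb[, j] <= box[2, j]
      assign[inside & is.na(assign)] <- g
    }
  } else if (!is.null(pc1_bins)) {
    pc1 <- emb[, 1]
    lo <- stats::quantile(pc1, tail_fraction, names = FALSE)
    hi <- stats::quantile(pc1, 1 - tail_fraction, names = FALSE)
    inside <- which(pc1 >= lo & pc1 <= hi)
    ## equal-count split along PC1
    ranks <- rank(pc1[inside], ties.method = "first")
    assign[inside] <- as.integer(
      cut(ranks, breaks = pc1_bins, labels = FALSE))
  } else stop("either regions or pc1_bins must be given")
  sizes <- table(assign)
  small <- as.integer(names(sizes)[sizes < min_group_size])
  if (length(small)) {
    warning(sprintf("dropping %d group(s) below min_group_size",
                    length(small)))
    assign[assign %in% small] <- NA_integer_
  }
  kept <- sort(unique(assign[!is.na(assign)]))
  assign <- match(assign, kept)
  groups <- lapply(seq_along(kept), function(g) which(assign == g))
  structure(list(assignments = assign, groups = groups,
                 mode = if (!is.null(regions)) "boxes" else "pc1_bins"),
            class = "group_selection")
}

#' Animate the reference along a principal axis
#'
#' Walks `n_frames` evenly spaced points along one embedding axis
#' (spanning a quantile range of the observed scores), back-projects
#' each to an amplitude vector and displaces the reference model.
#'
#' @param space A `conformational_space`.
#' @param model Reference [coarse_model()].
#' @param modeset Matching `normal_mode_set`.
#' @param axis Axis index (<= d).
#' @param n_frames Number of frames.
#' @param span Quantile range of scores covered (default c(0.05,
#'   0.95)); a single frame sits at score 0 (the mean conformation).
#' @param path Optional multi-model PDB output path.
#' @return List of [coarse_model()] frames (invisibly written to
#'   `path` when given).
#' @export
animate_space <- function(space, model, modeset, axis = 1L,
                          n_frames = 10L, span = c(0.05, 0.95),
                          path = NULL) {
  if (axis > nrow(space$components)) stop("axis exceeds embedding dim")
  scores <- if (n_frames == 1L) 0
  else seq(stats::quantile(space$embedding[, axis], span[1],
                           names = FALSE),
           stats::quantile(space$embedding[, axis], span[2],
                           names = FALSE),
           length.out = n_frames)
  frames <- lapply(scores, function(s) {
    sc <- numeric(nrow(space$components))
    sc[axis] <- s
    amp <- pca_backproject(space, sc)
    apply_amplitudes(model, modeset, as.numeric(amp))
  })
  if (!is.null(path)) write_model(frames, path)
  invisible(frames)
}

#' Write an embedding as a TSV table
#'
#' Columns: index, PC scores, provenance and (optionally) group.
#'
#' @param path Output path.
#' @param space A `conformational_space`.
#' @param selection Optional `group_selection`.
#' @export
write_space <- function(path, space, selection = NULL) {
  df <- data.frame(index = seq_len(nrow(space$embedding)) - 1L)
  for (j in seq_len(ncol(space$embedding)))
    df[[paste0("pc", j)]] <- space$embedding[, j]
  df$provenance <- space$provenance
  if (!is.null(selection)) df$group <- selection$assignments
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
plot.conformational_space <- function(x, selection = NULL, ...) {
  col <- if (!is.null(selection)) {
    g <- selection$assignments
    ifelse(is.na(g), "grey70", grDevices::hcl.colors(
      max(g, na.rm = TRUE), "Dark 3")[g])
  } else c(inferred = "#1b6ca8", hemnma = "#c2571a",
           ground_truth = "grey30")[x$provenance]
  graphics::plot(x$embedding[, 1],
                 if (ncol(x$embedding) > 1) x$embedding[, 2]
                 else seq_len(nrow(x$embedding)),
                 col = col, pch = 16, cex = 0.5,
                 xlab = "PC1", ylab = "PC2", ...)
  invisible(x)
}
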