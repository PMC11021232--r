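#' Degree synchrony between two visibility-graph layers
#'
#' In the multiplex view, each region's visibility graph is a layer sharing
#' its node set (the time points) with every other layer, so the degree
#' sequences of two layers are directly comparable time series. Degree
#' synchrony is their Pearson product-moment correlation
#' \deqn{S[D_x, D_y] = \frac{\sum_t (D_x(t)-\bar D_x)(D_y(t)-\bar D_y)}
#'   {n\,\sigma(D_x)\,\sigma(D_y)},}
#' a connectivity measure that asks whether degree fluctuations — bursts of
#' visibility driven by large-amplitude signal changes — co-occur across
#' regions.
#'
#' @param dx,dy degree sequences of equal length (>= 3), neither constant.
#' @return the correlation in \[-1, 1\].
#' @export
degree_synchrony <- function(dx, dy) {
  if (length(dx) != length(dy) || length(dx) < 3) {
    abort("degree sequences must have equal length >= 3",
          class = "vgfc_error_validation")
  }
  if (sd(dx) == 0 || sd(dy) == 0) {
    abort("degree synchrony undefined for a constant degree sequence",
          class = "vgfc_error_degenerate")
  }
  cor(dx, dy)
}

#' Degree-synchrony connectivity matrix of a parcellated scan
#'
#' Builds one visibility graph per region (layer), extracts its degree
#' sequence, and fills the region x region matrix of pairwise degree
#' synchronies with two-sided p-values from the t distribution with T - 2
#' degrees of freedom. Binary degrees are the default: the binary edge set
#' is invariant to positive affine rescaling of any region's series, so no
#' amplitude convention is needed. Weighted strengths (with z-scoring) are
#' available with `weighted = TRUE`.
#'
#' A region whose degree sequence is constant has undefined synchrony; its
#' row and column are set to `NA` with a warning, never silently dropped.
#'
#' @param ts frames x regions data frame or matrix.
#' @param weighted use weighted degree (strength) sequences.
#' @param zscore z-score regions before building weighted graphs (ignored
#'   for binary; default `TRUE`).
#' @return an object of class `vg_synchrony`: list with matrices `r`, `p`,
#'   logical `mask` (NULL until thresholded), `region_labels`, `n_frames`,
#'   `weighted`. Has [tidy()] and [autoplot()] methods.
#' @export
synchrony_matrix <- function(ts, weighted = FALSE, zscore = TRUE) {
  m <- ts_matrix(ts)
  if (weighted && zscore) m <- as.matrix(zscore_regions(m))
  degs <- if (weighted) {
    vapply(seq_len(ncol(m)), function(r)
      degree_sequence(visibility_graph(m[, r], weighted = TRUE), weighted = TRUE),
      numeric(nrow(m)))
  } else {
    vapply(seq_len(ncol(m)), function(r) as.numeric(vg_degree_cpp(m[, r])),
           numeric(nrow(m)))
  }
  colnames(degs) <- colnames(m)
  synchrony_from_degrees(degs, weighted = weighted)
}

# Shared tail: correlation + p-values from a frames x regions degree matrix.
synchrony_from_degrees <- function(degs, weighted = FALSE) {
  n <- nrow(degs)
  sds <- apply(degs, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("constant degree sequence, synchrony set to NA for: ",
                paste(colnames(degs)[sds == 0], collapse = ", ")))
  }
  degs[, sds == 0] <- NA_real_
  r <- suppressWarnings(cor(degs, use = "everything"))
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, mask = NULL,
                 region_labels = colnames(degs), n_frames = n,
                 weighted = weighted),
            class = "vg_synchrony")
}

#' Threshold a synchrony matrix
#'
#' Updates the retention mask without touching `r` or `p`. Methods:
#' `"fdr"` — Benjamini–Hochberg on the upper-triangle p-values at level
#' `level` (default 0.05); `"r"` — retain `|r| >= level`; `"density"` —
#' retain the top `level` fraction of edges by `|r|`.
#'
#' @param m a `vg_synchrony`.
#' @param method `"fdr"`, `"r"` or `"density"`.
#' @param level FDR q, absolute-r cutoff, or edge density, per method.
#' @return the `vg_synchrony` with its `mask` filled in (symmetric, `FALSE`
#'   diagonal; `NA` entries never retained).
#' @export
threshold_synchrony <- function(m, method = c("fdr", "r", "density"),
                                level = 0.05) {
  method <- match.arg(method)
  check_scalar(level, "level", lower = 0, upper = 1)
  R <- nrow(m$r)
  ut <- upper.tri(m$r)
  keep <- matrix(FALSE, R, R)
  if (method == "fdr") {
    if (is.null(m$p)) {
      abort("matrix has no p-values; use method 'r' or 'density', or recompute p",
            class = "vgfc_error_validation")
    }
    pv <- m$p[ut]
    q <- stats::p.adjust(pv, method = "BH")
    keep[ut] <- !is.na(q) & q <= level
  } else if (method == "r") {
    keep[ut] <- !is.na(m$r[ut]) & abs(m$r[ut]) >= level
  } else {
    rv <- abs(m$r[ut])
    k <- floor(level * sum(!is.na(rv)))
    if (k > 0) {
      cut <- sort(rv, decreasing = TRUE)[k]
      keep[ut] <- !is.na(rv) & rv >= cut
    }
  }
  m$mask <- keep | t(keep)
  m
}

#' Group-mean synchrony matrix
#'
#' Element-wise mean of the correlation matrices of several subjects
#' (the unthresholded `r`; thresholding, if any, is applied to the mean
#' afterwards). With `fisher = TRUE` the mean is taken on Fisher-z scale,
#' `tanh(mean(atanh(r)))`.
#'
#' @param matrices list of `vg_synchrony` objects with identical labels.
#' @param fisher average on the Fisher-z scale (default `FALSE`).
#' @param pvalues `"none"` (default) leaves `p` empty; `"t"` recomputes
#'   group-level p-values as a one-sample t-test of the subjects' Fisher-z
#'   correlations against zero (needs >= 3 matrices).
#' @return a `vg_synchrony` with the mean `r`; `mask` is `NULL`, `p` per
#'   `pvalues`.
#' @export
group_mean_synchrony <- function(matrices, fisher = FALSE,
                                 pvalues = c("none", "t")) {
  pvalues <- match.arg(pvalues)
  stopifnot(length(matrices) >= 1)
  labs <- matrices[[1]]$region_labels
  for (m in matrices) {
    if (!identical(m$region_labels, labs)) {
      abort("synchrony matrices have mismatched region labels",
            class = "vgfc_error_validation")
    }
  }
  arrs <- lapply(matrices, function(m) m$r)
  rbar <- if (fisher) {
    zs <- lapply(arrs, function(r) atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)))
    tanh(Reduce(`+`, zs) / length(zs))
  } else {
    Reduce(`+`, arrs) / length(arrs)
  }
  diag(rbar) <- 1
  p <- NULL
  if (pvalues == "t") {
    ns <- length(matrices)
    if (ns < 3) {
      abort("group-level p-values need at least 3 matrices",
            class = "vgfc_error_validation")
    }
    zs <- vapply(arrs, function(r)
      atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)), matrix(0, nrow(rbar), ncol(rbar)))
    zm <- apply(zs, c(1, 2), mean)
    zsd <- apply(zs, c(1, 2), sd)
    tt <- zm / (zsd / sqrt(ns))
    p <- 2 * pt(-abs(tt), df = ns - 1)
    diag(p) <- NA_real_
  }
  structure(list(r = rbar, p = p, mask = NULL, region_labels = labs,
                 n_frames = matrices[[1]]$n_frames,
                 weighted = matrices[[1]]$weighted),
            class = "vg_synchrony")
}

#' @export
print.vg_synchrony <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("<vg_synchrony> %d regions, %d frames, %s degrees\n",
              length(x$region_labels), x$n_frames,
              if (x$weighted) "weighted" else "binary"))
  cat(sprintf("  mean |r| = %.3f%s\n", mean(abs(off), na.rm = TRUE),
              if (is.null(x$mask)) "" else
                sprintf("; %d/%d edges retained",
                        sum(x$mask[upper.tri(x$mask)]), length(off))))
  invisible(x)
}

#' @rdname synchrony_matrix
#' @param x a `vg_synchrony` object.
#' @param ... unused.
#' @return `tidy()`: a long tibble of the upper triangle — `region_i`,
#'   `region_j`, `r`, `p`, `retained` (NA when unthresholded).
#' @exportS3Method generics::tidy
tidy.vg_synchrony <- function(x, ...) {
  R <- length(x$region_labels)
  ij <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(region_i = x$region_labels[ij[, 1]],
         region_j = x$region_labels[ij[, 2]],
         r = x$r[ij],
         p = if (is.null(x$p)) NA_real_ else x$p[ij],
         retained = if (is.null(x$mask)) NA else x$mask[ij]) |>
    arrange(.data$region_i, .data$region_j)
}

#' Write a synchrony matrix to disk
#'
#' Emits both a square labelled TSV of `r` and a long-format edge list
#' (`region_i`, `region_j`, `r`, `p`, `retained`).
#'
#' @param m a `vg_synchrony`.
#' @param path_matrix,path_edges output files (either may be `NULL` to skip).
#' @return `NULL`, invisibly.
#' @export
write_synchrony <- function(m, path_matrix = NULL, path_edges = NULL) {
  if (!is.null(path_matrix)) {
    df <- as_tibble(m$r, .name_repair = "minimal")
    names(df) <- m$region_labels
    readr::write_tsv(mutate(df, region = m$region_labels, .before = 1),
                     path_matrix)
  }
  if (!is.null(path_edges)) readr::write_tsv(tidy(m), path_edges)
  invisible(NULL)
}

#' @rdname synchrony_matrix
#' @param object a `vg_synchrony` object.
#' @exportS3Method ggplot2::autoplot
autoplot.vg_synchrony <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_i, y = .data$region_j,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "synchrony r",
                  title = "degree-synchrony connectivity (upper triangle)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
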