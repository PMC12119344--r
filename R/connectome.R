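#' Structural connectome container
#'
#' @param weights square nonnegative matrix of connection strengths
#'   (dimensionless); rescaled to max 1 so the global coupling `G` carries
#'   the overall magnitude. The diagonal is ignored by the coupling (regional
#'   self-excitation is the local recurrent term).
#' @param tract_lengths square symmetric nonnegative matrix (mm).
#' @param region_labels optional character vector.
#' @param centres optional n x 3 matrix of region coordinates (mm).
#' @param v_c conduction speed (mm/ms).
#' @param G global coupling factor.
#' @param normalize rescale weights to max 1.
#' @return list of class `connectome`.
#' @export
connectome <- function(weights, tract_lengths, region_labels = NULL,
                       centres = NULL, v_c = 3, G = 0.2, normalize = TRUE) {
  weights <- as.matrix(weights)
  tract_lengths <- as.matrix(tract_lengths)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("shape error: weights matrix is not square")
  if (!all(dim(tract_lengths) == c(n, n)))
    stop("shape error: tract-length matrix does not match weights")
  if (!is.numeric(weights) || anyNA(weights))
    stop("non-numeric entries in weights")
  if (!is.numeric(tract_lengths) || anyNA(tract_lengths))
    stop("non-numeric entries in tract lengths")
  if (any(weights < 0)) stop("negative connection weights rejected")
  if (any(tract_lengths < 0)) stop("negative tract lengths rejected")
  if (max(abs(tract_lengths - t(tract_lengths))) > 1e-8)
    stop("asymmetric tract lengths rejected")
  if (is.null(region_labels)) region_labels <- paste0("region_", seq_len(n))
  if (normalize && max(weights) > 0) weights <- weights / max(weights)
  structure(list(weights = weights, tract_lengths = tract_lengths,
                 region_labels = region_labels, centres = centres,
                 v_c = v_c, G = G, n_regions = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  dens <- mean(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Connectome: %d regions, density %.2f, v_c=%g mm/ms, G=%g\n",
              x$n_regions, dens, x$v_c, x$G))
  invisible(x)
}

#' Read a connectome from plain-text matrix files
#'
#' Reads the whitespace-delimited square-matrix dialect used by TVB-style
#' connectome bundles: `weights.txt` and `tract_lengths.txt`, with an
#' optional `centres.txt` (label x y z). A `.zip` bundle containing those
#' files is also accepted.
#'
#' @param path directory (or zip file) containing the matrices.
#' @param ... passed to [connectome()] (e.g. `v_c`, `G`).
#' @return a `connectome`.
#' @export
read_connectome <- function(path, ...) {
  if (length(path) == 1 && grepl("\\.zip$", path)) {
    tmp <- tempfile("connectome")
    utils::unzip(path, exdir = tmp)
    # allow a single top-level directory inside the zip
    inner <- list.dirs(tmp, recursive = FALSE)
    path <- if (file.exists(file.path(tmp, "weights.txt"))) tmp else inner[1]
  }
  wf <- file.path(path, "weights.txt")
  lf <- file.path(path, "tract_lengths.txt")
  if (!file.exists(wf)) stop("missing file: ", wf)
  if (!file.exists(lf)) stop("missing file: ", lf)
  w <- tryCatch(as.matrix(utils::read.table(wf)),
                warning = function(e) stop("non-numeric entries in ", wf),
                error = function(e) stop("non-numeric entries in ", wf))
  l <- tryCatch(as.matrix(utils::read.table(lf)),
                warning = function(e) stop("non-numeric entries in ", lf),
                error = function(e) stop("non-numeric entries in ", lf))
  if (!is.numeric(w)) stop("non-numeric entries in ", wf)
  if (!is.numeric(l)) stop("non-numeric entries in ", lf)
  labels <- NULL; centres <- NULL
  cf <- file.path(path, "centres.txt")
  if (file.exists(cf)) {
    cc <- utils::read.table(cf, stringsAsFactors = FALSE)
    labels <- as.character(cc[[1]])
    centres <- as.matrix(cc[, 2:4])
  }
  connectome(w, l, region_labels = labels, centres = centres, ...)
}

#' Write a connectome as plain-text matrix files
#'
#' Inverse of [read_connectome()]; matrices are written with full precision
#' so a round trip reproduces them bit-exactly.
#'
#' @param con a `connectome`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_connectome <- function(con, path) {
  stopifnot(inherits(con, "connectome"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m, f) {
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(path, f), row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  fmt(con$weights, "weights.txt")
  fmt(con$tract_lengths, "tract_lengths.txt")
  if (!is.null(con$centres)) {
    cc <- data.frame(label = con$region_labels,
                     format(con$centres, digits = 17, trim = TRUE))
    utils::write.table(cc, file.path(path, "centres.txt"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Generate a synthetic connectome
#'
#' Stands in for a tractography-derived structural connectome so that
#' whole-brain simulations need no external download: region centres are
#' drawn uniformly in a sphere of cortical extent, tract lengths are the
#' Euclidean inter-centre distances (hence symmetric and triangle-inequality
#' consistent), and weights are symmetric, sparse with the requested density,
#' with log-normal magnitudes normalised to max 1. Deterministic under
#' `seed`. This synthetic object emulates the size and sparsity of a 68-region
#' cortical parcellation, not the topology of any real brain.
#'
#' @param n_regions number of regions (>= 2).
#' @param density fraction of connected (unordered) region pairs.
#' @param seed RNG seed.
#' @param radius sphere radius for the centres (mm).
#' @param v_c,G conduction speed (mm/ms) and global coupling.
#' @return a `connectome`.
#' @examples
#' con <- synthetic_connectome(20, density = 0.3, seed = 1)
#' @export
synthetic_connectome <- function(n_regions = 68, density = 0.3, seed = 1,
                                 radius = 70, v_c = 3, G = 0.2) {
  stopifnot(n_regions >= 2, density > 0, density <= 1)
  set.seed(seed)
  # uniform in a ball: rejection-free via radius ~ U^(1/3)
  u <- matrix(stats::rnorm(3 * n_regions), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  centres <- u * radius * stats::runif(n_regions)^(1 / 3)
  lengths <- as.matrix(stats::dist(centres))
  w <- matrix(0, n_regions, n_regions)
  ut <- upper.tri(w)
  conn <- stats::runif(sum(ut)) < density
  mag <- stats::rlnorm(sum(ut), meanlog = 0, sdlog = 1)
  w[ut] <- ifelse(conn, mag, 0)
  w <- w + t(w)
  connectome(w, lengths,
             region_labels = sprintf("synthetic_region_%02d", seq_len(n_regions)),
             centres = centres, v_c = v_c, G = G)
}
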