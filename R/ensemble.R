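#' @importFrom stats rnorm runif sd var cov lm coef quantile qnorm dnorm integrate
#' @importFrom utils head tail
NULL

#' Construct an embryo ensemble
#'
#' An `embryo_ensemble` holds one-dimensional expression profiles for a set of
#' embryos that share a gene list and a common grid of scaled positions
#' `xs = x/L`. Per embryo it stores the anterior-posterior length `L` (micron),
#' a developmental time `t` (minutes), and one concentration vector per gene in
#' normalized (unit-maximum) units.
#'
#' The grid is cell-centered: `xs_j = (j - 1/2) / n_grid`, so that binning the
#' axis into widths that divide 1 (e.g. 0.01 with the default 1000-point grid)
#' puts exactly the same number of grid samples in every bin.
#'
#' @param xs numeric grid of scaled positions, strictly increasing in (0, 1).
#' @param lengths numeric vector of embryo lengths in micron, all positive.
#' @param times numeric vector of developmental times in minutes.
#' @param genes character vector of gene names.
#' @param profiles numeric array `n_embryos x n_grid x n_genes`.
#' @param params list of provenance (generator parameters, seed); optional.
#' @return An object of class `embryo_ensemble`.
#' @export
embryo_ensemble <- function(xs, lengths, times, genes, profiles, params = list()) {
  n <- length(lengths)
  if (n < 1L) stop("ensemble needs at least one embryo")
  if (length(times) != n) stop("lengths and times must have the same length")
  if (any(lengths <= 0)) stop("embryo lengths must be positive")
  if (any(diff(xs) <= 0) || any(xs <= 0) || any(xs >= 1))
    stop("xs grid must be strictly increasing within (0, 1)")
  profiles <- as.array(profiles)
  if (length(dim(profiles)) == 2L) dim(profiles) <- c(dim(profiles), 1L)
  if (!all(dim(profiles) == c(n, length(xs), length(genes))))
    stop("profiles must be an n_embryos x n_grid x n_genes array")
  dimnames(profiles) <- list(NULL, NULL, genes)
  structure(
    list(xs = xs, lengths = lengths, times = times, genes = genes,
         profiles = profiles, params = params),
    class = "embryo_ensemble"
  )
}

#' Number of embryos in an ensemble
#' @param ensemble an `embryo_ensemble`.
#' @return integer count.
#' @export
n_embryos <- function(ensemble) length(ensemble$lengths)

#' @export
print.embryo_ensemble <- function(x, ...) {
  cat(sprintf("embryo_ensemble: %d embryos, %d genes (%s), %d grid points\n",
              n_embryos(x), length(x$genes), paste(x$genes, collapse = ", "),
              length(x$xs)))
  cat(sprintf("  length: mean %.1f um, cv %.4f; time range [%.1f, %.1f] min\n",
              mean(x$lengths), sd(x$lengths) / mean(x$lengths),
              min(x$times), max(x$times)))
  if (!is.null(x$params$mode))
    cat(sprintf("  generator mode: %s\n", x$params$mode))
  invisible(x)
}

#' Convert an ensemble to a long-format data frame
#'
#' Columns: `embryo_id`, `L_um`, `t_min`, `gene`, `xs`, `g`.
#'
#' @param x an `embryo_ensemble`.
#' @param row.names,optional,... ignored (base generic signature).
#' @return a `data.frame` with one row per (embryo, gene, grid point).
#' @export
as.data.frame.embryo_ensemble <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- n_embryos(x); m <- length(x$xs); k <- length(x$genes)
  data.frame(
    embryo_id = rep(seq_len(n), times = m * k),
    L_um = rep(x$lengths, times = m * k),
    t_min = rep(x$times, times = m * k),
    gene = rep(x$genes, each = n * m),
    xs = rep(rep(x$xs, each = n), times = k),
    g = as.vector(x$profiles)
  )
}

#' Write / read an ensemble as a delimited long-format table
#'
#' The on-disk format is a plain tab-separated table with columns
#' `embryo_id, L_um, t_min, gene, xs, g`, one row per (embryo, gene, grid
#' point). For large ensembles where a text table is too slow, pass the
#' `embryo_ensemble` object to [saveRDS()] instead; [read_ensemble()] and
#' `readRDS()` round-trip both representations.
#'
#' @param ensemble an `embryo_ensemble`.
#' @param path file path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble` returns
#'   an `embryo_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  data.table::fwrite(as.data.frame(ensemble), path, sep = "\t")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  genes <- unique(dt$gene)
  ids <- unique(dt$embryo_id)
  xs <- sort(unique(dt$xs))
  n <- length(ids); m <- length(xs); k <- length(genes)
  if (nrow(dt) != n * m * k) stop("table is not a complete embryo x grid x gene grid")
  ord <- order(match(dt$gene, genes), dt$xs, dt$embryo_id)
  profiles <- array(dt$g[ord], dim = c(n, m, k), dimnames = list(NULL, NULL, genes))
  meta <- unique(dt[, c("embryo_id", "L_um", "t_min")])
  data.table::setorderv(meta, "embryo_id")
  embryo_ensemble(xs, meta$L_um, meta$t_min, genes, profiles)
}

#' Extract a subset of embryos
#'
#' @param ensemble an `embryo_ensemble`.
#' @param idx integer indices of embryos to keep (duplicates allowed, e.g. for
#'   bootstrap resampling).
#' @return an `embryo_ensemble` with the selected embryos.
#' @export
subset_embryos <- function(ensemble, idx) {
  embryo_ensemble(ensemble$xs, ensemble$lengths[idx], ensemble$times[idx],
                  ensemble$genes,
                  ensemble$profiles[idx, , , drop = FALSE],
                  ensemble$params)
}

# Evaluate code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored on exit. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministically derive `n` independent sub-seeds from one master seed, so
# that subsampling, bootstrap and shuffle streams are separately reproducible.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
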