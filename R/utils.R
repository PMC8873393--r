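#' Derive a reproducible sub-stream seed
#'
#' All randomness in the simulator flows from one user seed through
#' counter-based sub-streams, one per gene (or per restart, per stage), so
#' that enlarging a simulation does not perturb the draws of entities that
#' were already present. The derived seed is always in `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param ... Further integer counters (gene index, stage id, ...).
#' @return A single integer seed.
#' @export
#' @examples
#' stream_seed(1, 5)
#' stream_seed(1, 5, 2)
stream_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  stopifnot(length(ks) >= 1, all(is.finite(ks)))
  m <- 2147483647 # 2^31 - 1, keeps every intermediate below 2^53
  s <- 0
  for (k in ks) {
    s <- (s * 69069 + (abs(as.double(k)) %% m) + 1) %% m
  }
  as.integer(s)
}

# run expr under a local RNG state seeded with `seed`; restores global state
with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number %s %s",
      name, if (strict) ">" else ">=", format(min)
    ), class = "uvtx_config_error")
  }
  invisible(x)
}

# columns of `tbl` that hold per-sample values (everything except id columns)
sample_columns <- function(tbl, id_cols = "gene_id") {
  setdiff(names(tbl), id_cols)
}

# genes x samples numeric matrix from a tibble with a gene_id column
as_count_matrix <- function(tbl, id_col = "gene_id") {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m, id_col = "gene_id") {
  out <- as_tibble(m)
  out[[id_col]] <- rownames(m)
  out[, c(id_col, setdiff(names(out), id_col))]
}
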