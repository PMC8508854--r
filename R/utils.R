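# Internal helpers shared across modules.

#' Convert a probe-by-sample tibble to a numeric matrix
#'
#' Methylation matrices travel through the package as tibbles whose first
#' column is `probe_id` and whose remaining columns are samples. This strips
#' the id column into rownames for linear algebra.
#'
#' @param x A tibble with a `probe_id` first column.
#' @return A numeric matrix with probe ids as rownames.
#' @keywords internal
#' @noRd
mat_of <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "probe_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$probe_id
  m
}

#' @noRd
tbl_of <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)), out)
}

#' @noRd
check_aligned <- function(a, b, what = "matrices") {
  if (!identical(a$probe_id, b$probe_id) ||
      !identical(names(a), names(b))) {
    stop(what, " must share identical probe and sample ordering",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Local RNG scope: runs `expr` under `seed` and restores the caller's RNG
# state afterwards, so generators never perturb the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
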