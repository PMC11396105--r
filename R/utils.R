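#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows rename n distinct across
#'   row_number slice_head desc if_else count pull
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map2 pmap pmap_dbl
#' @importFrom stats p.adjust binom.test fisher.test cor.test rpois rbinom
#'   rnbinom rlnorm runif setNames
#' @importFrom utils head modifyList
NULL

# Derive a reproducible sub-stream seed from a master seed and a stable label.
# Horner hash mod (2^31 - 1) keeps the result inside R's integer range.
stream_seed <- function(seed, label) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer((abs(seed) %% m * 7919 + h) %% m)
}

with_stream_seed <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, label))
  force(code)
}

assert_prop <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1].", name),
          class = "hybridscope_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x == trunc(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a %s integer.", name,
                  if (positive) "positive" else "non-negative"),
          class = "hybridscope_config_error")
  }
  invisible(x)
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
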