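# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Clip scores onto the label scale [0, 1]; preserves dim and dimnames.
clip01 <- function(m) pmin(pmax(m, 0), 1)

# Locale-independent lexicographic sort (C collation), so entity order is
# reproducible across machines.
sort_ids <- function(ids) sort(unique(ids), method = "radix")

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("crnmf_validation_error", "error", "condition")))
}

stop_parse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("crnmf_parse_error", "crnmf_validation_error",
                                "error", "condition")))
}

stop_file <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("crnmf_file_error", "error", "condition")))
}

stop_numeric <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("crnmf_numeric_error", "error", "condition")))
}

check_matrix_finite <- function(m, name) {
  if (!all(is.finite(m))) stop_numeric("non-finite values in %s", name)
  invisible(m)
}
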