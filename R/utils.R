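# Shared helpers: typed conditions, local RNG scope, small formatting utilities.

#' @noRd
ps_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "phosphoscreen_error")))
}

#' @noRd
ps_assert <- function(ok, msg, class = "ps_error_invalid") {
  if (!isTRUE(ok)) ps_stop(msg, class)
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Content hash used for pipeline checkpoints: serialize to a temp file and
# md5sum it (version 2 serialization for cross-session stability).
#' @noRd
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' @noRd
file_hash <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "", ...)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
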