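#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix readMM writeMM sparseMatrix
#' @importFrom stats cor pt phyper p.adjust rnbinom rnorm rgamma runif
#'   wilcox.test hclust cutree dist sd setNames qnorm
#' @importFrom utils read.delim write.table
NULL

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, off = 4L)

#' Set or query the pipeline log level
#'
#' Pipeline stages log input shapes, the parameters in force and the number
#' of records surviving each filter. Levels: `"debug"`, `"info"`,
#' `"warning"`, `"off"`.
#'
#' @param level New level; omit to query the current one.
#' @return The current (possibly new) level, invisibly when setting.
#' @export
st_log_level <- function(level = NULL) {
  if (is.null(level)) {
    return(getOption("stcomm.log_level", "info"))
  }
  level <- match.arg(level, names(.log_levels))
  options(stcomm.log_level = level)
  invisible(level)
}

st_log <- function(fmt, ..., level = "info") {
  if (.log_levels[[level]] >= .log_levels[[st_log_level()]]) {
    message("[stcomm] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = env)
      } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Benjamini-Hochberg step-up adjustment; thin named wrapper so that every
# "adjusted p-value" in the toolkit goes through one audited call.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
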