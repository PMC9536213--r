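#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n distinct across
#' @importFrom stats rnorm runif rpois optim var sd fft setNames predict
#' @importFrom utils read.delim tail head
NULL

# Path to a packaged data file
tcsim_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tcsim")
  if (!nzchar(path)) abort(paste0("packaged data file not found: ", file))
  path
}

read_tsv_strict <- function(path) {
  as_tibble(read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                       check.names = FALSE))
}

#' Run an expression with a local random seed
#'
#' Evaluates `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so that library code does not disturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# positive truncated normal draw: floor at `floor_frac` of the mean
rnorm_trunc <- function(n, mean, sd, floor_frac = 0.01) {
  x <- rnorm(n, mean, sd)
  pmax(x, floor_frac * abs(mean))
}

round_half_even <- function(x) round(x) # base R rounds half to even

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    abort(paste0("`", name, "` must be a finite scalar"))
  invisible(x)
}
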