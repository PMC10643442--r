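# Internal helpers: seeding, validation, design matrices.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' All randomness in dyadmr flows from one master seed; each operation draws
#' from its own substream so that adding a stage never perturbs another
#' stage's random numbers.  The substream seed is a stable hash of the master
#' seed and the operation name (no external dependency, 31-bit range).
#'
#' @param seed master integer seed.
#' @param op character operation label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "simulate_genotypes")
substream_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (b in utf8ToInt(op)) h <- (h * 31 + b) %% m
  s <- (abs(as.numeric(seed)) %% m) * 48271 %% m
  as.integer((s + h) %% (m - 1) + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_param <- function(...) {
  stop(structure(class = c("dyadmr_parameter_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_schema <- function(...) {
  stop(structure(class = c("dyadmr_schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

require_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_schema(what, " is missing required column(s): ",
                paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Build a numeric design matrix (no intercept column) from a covariate
# data.frame/matrix/vector; factors and characters are one-hot encoded
# dropping the first level.  NULL -> zero-column matrix.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.vector(covariates) && !is.list(covariates)) {
    covariates <- data.frame(covariate = covariates)
  }
  if (is.matrix(covariates)) {
    storage.mode(covariates) <- "double"
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
    }
    if (nrow(covariates) != n) stop_schema("covariates have wrong length")
    return(covariates)
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop_schema("covariates have wrong length")
  for (j in names(covariates)) {
    if (is.character(covariates[[j]])) covariates[[j]] <- factor(covariates[[j]])
  }
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE] # drop intercept; lost rows impossible: caller handles NA
}

z975 <- function() stats::qnorm(0.975)

# Two-sided normal p-value for estimate/se.
norm_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
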