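`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream seeded to `seed`, then
#' restores the previous stream so callers are unaffected.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
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
  set.seed(seed)
  code
}

# Deterministic, locale-independent hash of a string into [0, 2^31 - 2].
# All arithmetic stays below 2^53 so it is exact in doubles.
string_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(x))) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a stage seed from a master seed
#'
#' Pipeline stages (embedding, cluster-count selection, fuzzy fit, per-cluster
#' sub-analyses) each get their own seed derived deterministically from one
#' master seed, a stage name, and a population label, so strata runs are
#' independent yet fully reproducible.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @param label Character population label (e.g. `"F/65-84"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage, label = "") {
  h <- string_hash(paste(stage, label, sep = ":"))
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + h) %% 2147483646 + 1)
}

# Cheap deterministic fingerprint of a numeric object, recorded in run
# manifests so intermediate artifacts can be compared across runs.
fingerprint <- function(x) {
  v <- as.numeric(x)
  if (length(v) == 0) return("0:0")
  w <- (seq_along(v) - 1) %% 997 + 1
  sprintf("%d:%.10e", length(v), sum(v * w))
}
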