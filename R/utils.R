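# Internal helpers shared across modules.

# Canonical protein/gene identifier form: uppercase, whitespace-stripped.
canonicalizeIds <- function(ids) {
  toupper(trimws(as.character(ids)))
}

.checkIdsNonEmpty <- function(ids, what = "ID") {
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad) > 0L) {
    stop(what, " missing or empty at line ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  invisible(ids)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL leaves the RNG alone.
withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derived per-replicate seed so replicate r is reproducible independently of
# evaluation order. Plain integer arithmetic, pinned below 2^31.
repSeed <- function(seed, r) {
  if (is.null(seed) || is.na(seed)) return(NULL)
  as.integer((as.numeric(seed) + 10007 * as.numeric(r)) %% 2147483629) + 1L
}

# Row-wise minima of a numeric matrix (small column counts).
.rowMins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# sample() that never falls into the length-1 integer trap.
.sampleVec <- function(x, k) {
  x[sample.int(length(x), k)]
}

.asMembers <- function(x) {
  if (methods::is(x, "TargetSet")) members(x) else unique(canonicalizeIds(x))
}
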