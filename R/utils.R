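# Internal helpers shared across modules.

# Deterministic 31-ary string hash into [0, 2^31 - 2]; used to derive
# per-comparison child seeds so adding a comparison to a screen does not
# perturb the null distributions of the others.
string_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483646
  h
}

child_seed <- function(master_seed, key) {
  as.integer((as.numeric(master_seed) + string_hash(key)) %% 2147483646) + 1L
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL uses the current stream (caller is responsible for determinism).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer, not %s.",
                  name, deparse(substitute(x))))
  }
}

# Merge already-linearised half-open intervals. Touching intervals coalesce.
merge_linear <- function(s, e) {
  if (length(s) == 0L) return(list(s = numeric(0), e = numeric(0)))
  o <- order(s, e)
  s <- s[o]
  e <- e[o]
  cm <- cummax(e)
  new <- c(TRUE, s[-1L] > cm[-length(cm)])
  idx <- which(new)
  list(s = s[idx], e = cm[c(idx[-1L] - 1L, length(e))])
}

# Closure returning covered bp of a merged, sorted interval list up to
# coordinate x (vectorised). The workhorse behind all overlap arithmetic:
# overlap of [qs, qe) with the set is covered(qe) - covered(qs).
coverage_fun <- function(s, e) {
  cum <- if (length(s)) cumsum(e - s) else numeric(0)
  function(x) {
    if (length(s) == 0L) return(numeric(length(x)))
    i <- findInterval(x, s)
    out <- numeric(length(x))
    p <- i > 0L
    ii <- i[p]
    out[p] <- cum[ii] - pmax(0, e[ii] - x[p])
    out
  }
}

# Stepwise-signal analogue of coverage_fun: integral of a non-overlapping
# run-length track up to x.
integral_fun <- function(s, e, v) {
  cum <- if (length(s)) cumsum(v * (e - s)) else numeric(0)
  function(x) {
    if (length(s) == 0L) return(numeric(length(x)))
    i <- findInterval(x, s)
    out <- numeric(length(x))
    p <- i > 0L
    ii <- i[p]
    out[p] <- cum[ii] - v[ii] * pmax(0, e[ii] - x[p])
    out
  }
}
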