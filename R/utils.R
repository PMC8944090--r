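# internal helpers shared across modules

# two-sided normal p, floored at the smallest normal double so p stays in (0, 1]
p_from_z <- function(z) pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)

# empirical p with the (1 + x)/(n + 1) convention so p is never 0
p_empirical <- function(n_geq, n_sim) (1 + n_geq) / (n_sim + 1)

ci_mult <- 1.96

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# derive a child RNG seed from a parent seed and a stream label,
# kept below 2^31 so it is always a valid R integer seed
child_seed <- function(seed, stream) {
  stream_num <- sum(utf8ToInt(as.character(stream))) %% 104729
  as.integer((as.numeric(seed) * 48271 + stream_num * 1009 + 17) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "G" & oa == "C") | (ea == "C" & oa == "G")
}

allele_complement <- function(a) {
  unname(c(A = "T", T = "A", G = "C", C = "G")[a])
}
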