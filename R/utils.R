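# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code does not perturb user
# simulations.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Spearman rho and two-sided p for one pair of complete vectors.
# Exact null distribution (via cor.test) for n <= 9 without ties, else the
# t-approximation on rho. Constant input yields rho 0 / p 1; the caller is
# responsible for warning.
spearman_pair <- function(x, y) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(rho = 0, p = 1, degenerate = 1))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    return(c(rho = unname(ct$estimate), p = ct$p.value, degenerate = 0))
  }
  r <- stats::cor(x, y, method = "spearman")
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  c(rho = r, p = p, degenerate = 0)
}

# Align an abundance table with metadata: returns list(values, case, control)
# where values has only samples present in the metadata.
align_with_metadata <- function(table, meta) {
  stopifnot(inherits(table, "abundance_table"), inherits(meta, "sample_metadata"))
  common <- intersect(ab_samples(table), meta$sample_id)
  if (length(common) < 4) {
    stop("fewer than 4 samples shared between table and metadata", call. = FALSE)
  }
  grp <- split_groups(meta)
  list(values = ab_values(table)[, common, drop = FALSE],
       case = intersect(common, grp$case),
       control = intersect(common, grp$control))
}
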