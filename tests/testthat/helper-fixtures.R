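# Small in-code fixtures shared across test files.

# A tiny dataset built by hand: `per_group` samples in each of the five
# groups, expression = baseline + planted group offsets + N(0, sd).
tiny_dataset <- function(n_genes = 20, per_group = 4, offsets = NULL,
                         sd = 0.3, seed = 42) {
  set.seed(seed)
  groups <- rep(stage_levels(), each = per_group)
  n <- length(groups)
  if (is.null(offsets)) offsets <- matrix(0, n_genes, 4)
  shift <- cbind(0, offsets)[, match(groups, stage_levels()), drop = FALSE]
  exprs <- matrix(rnorm(n_genes * n, mean = 8, sd = sd), n_genes, n) + shift
  rownames(exprs) <- sprintf("g%03d", seq_len(n_genes))
  samples <- tibble::tibble(
    barcode = sprintf("TCGA-AA-%04d-%sA-11R-A131-07", seq_len(n),
                      ifelse(groups == "control", "11", "01")),
    sample_type = ifelse(groups == "control", "normal", "tumor"),
    stage = ifelse(groups == "control", NA_character_, groups),
    group = groups)
  stage_dataset(exprs, samples)
}

# Brute-force Benjamini-Hochberg step-up oracle: sort, p * n / rank,
# cumulative minimum from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummin((p[o] * n / seq_len(n))[n:1])[n:1])
  out <- numeric(n)
  out[o] <- adj
  out
}

# Normal-equations least-squares oracle.
ols_oracle <- function(X, y) unname(drop(solve(t(X) %*% X, t(X) %*% y)))

# Per-row sample variance via the direct formula.
row_sample_var <- function(m) apply(m, 1, stats::var)

# Adjacent-pair brute-force monotonicity oracle.
monotone_oracle <- function(m) {
  up <- all(m[2] > m[1], m[3] > m[2], m[4] > m[3], m[5] > m[4])
  down <- all(m[2] < m[1], m[3] < m[2], m[4] < m[3], m[5] < m[4])
  if (up) "UP" else if (down) "DOWN" else "none"
}
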