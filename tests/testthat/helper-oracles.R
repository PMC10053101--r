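# Independent oracles kept deliberately naive.

# Closed-form OLS via the normal equations, with coefficient SEs and
# two-tailed t-test p-values.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- as.numeric(beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  list(beta = as.numeric(beta), se = se, t = tval, p = pval,
       df = n - p)
}

# Exhaustive window scan for N-X(!=P)-[S/T] sequons.
sequon_oracle <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(max(length(ch) - 2, 0))) {
    if (ch[i] == "N" && ch[i + 1] != "P" && ch[i + 2] %in% c("S", "T")) {
      hits <- c(hits, i)
    }
  }
  hits
}

# Exhaustive least-squares grid refinement for a Michaelis-Menten fit:
# for each candidate Km the conditionally optimal Vmax is closed-form.
mm_grid_oracle <- function(S, v, km_range, coarse_by = 10, fine_by = 0.1) {
  sse_at <- function(km) {
    vm <- sum(v * S / (km + S)) / sum((S / (km + S))^2)
    c(km = km, vm = vm, sse = sum((v - vm * S / (km + S))^2))
  }
  coarse <- t(sapply(seq(km_range[1], km_range[2], by = coarse_by), sse_at))
  best <- coarse[which.min(coarse[, "sse"]), ]
  fine <- t(sapply(seq(best["km"] - coarse_by, best["km"] + coarse_by,
                       by = fine_by), sse_at))
  fine[which.min(fine[, "sse"]), ]
}

# A thermal series lying exactly on the line J = intercept + slope * (J/I):
# J = intercept * I / (I - slope), valid for temperatures above the slope.
collinear_thermal_series <- function(intercept, slope,
                                     temps = c(40, 50, 60, 70, 80)) {
  stopifnot(all(temps > slope))
  thermal_series(temps, intercept * temps / (temps - slope))
}

random_aa_string <- function(n) {
  paste(sample(names(apkin::aa_residue_masses()), n, replace = TRUE),
        collapse = "")
}
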