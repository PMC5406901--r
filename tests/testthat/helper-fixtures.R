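# shared fixtures and independent oracles, built in code at test time

# small hand-built tree: root + one daughter pair, arbitrary readouts
tiny_tree <- function(latent = NULL) {
  lineage_tree(list(
    cell_record(0, 1, 30, c(10, 20, 30), c(0.5, 1.2, 2.9), latent = latent),
    cell_record(1, 1, 30, c(15, 30), c(3.1, 4.0), latent = latent),
    cell_record(1, 2, 30, c(15, 30), c(2.2, 3.3), latent = latent)))
}

# deterministic single-cell "tree": known initial state, no branching
single_cell_tree <- function(obs_times = c(5, 10, 15), readouts = c(1, 2, 3),
                             lifetime = 30) {
  lineage_tree(list(cell_record(0, 1, lifetime, obs_times, readouts)))
}

# a branching model whose root state is degenerate (fixed type ON, D=F=0):
# with theta1 = 1 or theta3 = 1 the whole tree is deterministic
deterministic_branching <- function(type_on = TRUE) {
  branching_model(theta1 = if (type_on) 0 else 1, theta2 = 0,
                  theta3 = if (type_on) 0 else 1, theta4 = 0,
                  root = list(p_on = as.numeric(type_on), D0 = 0, F0 = 0))
}

# fine-grid forward-Euler integration of the reporter ODE pair driven by a
# piecewise-constant production rate; independent of the closed forms
euler_reporter <- function(D0, F0, alpha_fun, delta, m, T, h = 1e-4) {
  n <- ceiling(T / h)
  h <- T / n
  D <- D0; F <- F0
  t <- 0
  for (i in seq_len(n)) {
    al <- alpha_fun(t)
    Dn <- D + h * (al - (delta + m) * D)
    F <- F + h * (m * D - delta * F)
    D <- Dn
    t <- t + h
  }
  list(D = D, F = F)
}

# independent Dirichlet log-density via the stick-breaking Beta factorization
# (three components): x ~ Dir(a) iff x1 ~ Beta(a1, a2+a3) and
# x2/(1-x1) ~ Beta(a2, a3), with the change-of-variable factor 1/(1-x1)
ldirichlet_sb <- function(x, a) {
  dbeta(x[1], a[1], a[2] + a[3], log = TRUE) +
    dbeta(x[2] / (1 - x[1]), a[2], a[3], log = TRUE) - log(1 - x[1])
}

# MCSE of a chain's mean by non-overlapping batch means
batch_mcse <- function(x, n_batch = 50) {
  bs <- floor(length(x) / n_batch)
  bm <- vapply(seq_len(n_batch),
               function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(bm) / sqrt(n_batch)
}
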