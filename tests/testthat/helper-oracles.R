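# Independent oracles used across the suite. These re-derive the model
# arithmetic by hand so they share no code path with the package.

# hand-written derivatives of the batch model (growth with Haldane +
# product-inhibition terms, net death; Luedeking-Piret on the positive part
# of dX/dt; substrate balance with maintenance; exhaustion clamps)
oracle_derivs <- function(y, p) {
  X <- y[1]; S <- max(y[2], 0); PBa <- y[3]; PAa <- y[4]
  P <- PBa + PAa
  base <- max(min(1 - P / p$P_d, 1), 0)
  mu <- p$mu_m * S / (S + p$K_S + S^2 / p$K_I) * base^p$i
  dX <- (mu - p$K_d) * X
  if (S > 0) {
    dXp <- max(dX, 0)
    dBa <- p$alpha_Ba * dXp + p$beta_Ba * X
    dAa <- p$alpha_Aa * dXp + p$beta_Aa * X
    dS <- -(dXp / p$Y_X + dBa / p$Y_Ba + dAa / p$Y_Aa + p$m_S * X)
  } else {
    dX <- -p$K_d * X; dBa <- 0; dAa <- 0; dS <- 0
  }
  c(dX, dS, dBa, dAa)
}

# classical fixed-step RK4 on the hand-written derivatives
oracle_rk4 <- function(p, y0, t_eval, h = 0.01) {
  t <- t_eval[1]
  y <- y0
  out <- matrix(NA_real_, length(t_eval), 4)
  out[1, ] <- y
  for (k in 2:length(t_eval)) {
    target <- t_eval[k]
    while (t < target - 1e-12) {
      step <- min(h, target - t)
      k1 <- oracle_derivs(y, p)
      k2 <- oracle_derivs(y + step / 2 * k1, p)
      k3 <- oracle_derivs(y + step / 2 * k2, p)
      k4 <- oracle_derivs(y + step * k3, p)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y <- pmax(y, 0)
      t <- t + step
    }
    out[k, ] <- y
  }
  colnames(out) <- c("X", "S", "P_Ba", "P_Aa")
  out
}

# assemble a dram_chain-shaped object from externally generated draws, for
# testing envelope/diagnostic plumbing against known distributions
pseudo_chain <- function(samples, s2 = NULL, burn_in = 0) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  structure(list(
    samples = samples,
    s2chain = s2 %||% rep(1, n),
    logpost = rep(0, n),
    accept_stage1 = n, accept_stage2 = 0L, n_stage2_tries = 0L,
    config = mcmc_config(n_steps = n, seed = 1, burn_in = burn_in),
    flagged = NULL
  ), class = "dram_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small convenience: a monotone synthetic survival table
toy_survival_table <- function() {
  survival_table("toy", c(50, 55, 60, 65, 70, 75, 80),
                 rep(6000, 7), c(600, 1500, 2700, 3900, 5000, 5600, 5940))
}
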