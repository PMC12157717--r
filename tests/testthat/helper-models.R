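# shared small fixtures, built in code

model_1to1 <- function(logK = 6) {
  eq_model(c("M", "L"),
           species = list(list(name = "ML", stoich = c(M = 1, L = 1),
                               log_beta = logK)))
}

model_nacl <- function(Ks = 2e-9, K_IP = 0) {
  sp <- if (K_IP > 0)
    list(list(name = "NaCl", stoich = c(Na = 1, Cl = 1),
              log_beta = log10(K_IP)))
  eq_model(c("Na", "Cl"), species = sp,
           solids = list(list(name = "NaCl_s", stoich = c(Na = 1, Cl = 1),
                              log_Ks = log10(Ks))))
}

model_dimer <- function(K_dim = 1e2) {
  eq_model("A", species = list(list(name = "A2", stoich = c(A = 2),
                                    log_beta = log10(K_dim))))
}

# closed-form 1:1 oracle: x + beta x^2 = T at equal totals
free_1to1_equal <- function(beta, total) {
  (-1 + sqrt(1 + 4 * beta * total)) / (2 * beta)
}

# a reproducible set of random one-unknown models over the study regimes
random_one_unknown <- function(n, seed = 101) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kind <- sample(c("bind", "dimer", "pair"), 1)
    beta <- 10^runif(1, 0, 8)
    tot <- 10^runif(2, -6, -2)
    if (kind == "dimer")
      list(model = model_dimer(beta), totals = c(A = tot[1]))
    else
      list(model = model_1to1(log10(beta)),
           totals = c(M = tot[1], L = tot[2]))
  })
}
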