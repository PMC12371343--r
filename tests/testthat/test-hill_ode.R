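two_gene_chain <- function(w = 3, u = c(1.5, 0), tau = 0.3) {
  net <- gene_network(c("g1", "g2"), rbind(c("g1", "g2")))
  W <- matrix(0, 2, 2, dimnames = list(net$genes, net$genes))
  W["g1", "g2"] <- w
  list(net = net,
       params = hill_params(W, u, tau, list(b1 = c(0.1, 0.1))))
}

test_that("the Hill right-hand side matches hand evaluation", {
  # no edges, u = 0, x = 0: the origin is a fixed point
  p0 <- hill_params(matrix(0, 2, 2), c(0, 0), 1, list(b1 = c(0, 0)))
  expect_equal(hill_rhs(c(0, 0), p0), c(0, 0))
  # activating edge j -> i, W = 2, x_j = 0.5: H_i = 0.25/1.25 = 0.2
  W <- matrix(c(0, 0, 2, 0), 2, 2)  # W[1, 2]: gene 1 regulates gene 2
  p <- hill_params(W, c(0, 0), 1, list(b1 = c(0.5, 0.1)))
  expect_equal(hill_rhs(c(0.5, 0.1), p)[2], 0.2 - 0.1)
  # inhibiting edge with saturated repressor: H_i = 0, dx_i = -x_i / tau
  Wn <- matrix(c(0, 0, -1, 0), 2, 2)
  pn <- hill_params(Wn, c(0, 0), 2, list(b1 = c(1, 0.4)))
  expect_equal(hill_rhs(c(1, 0.4), pn)[2], -0.4 / 2)
})

test_that("H stays in [0, 1) for nonnegative states and drives", {
  set.seed(10)
  for (rep in 1:50) {
    m <- sample(2:5, 1)
    W <- matrix(runif(m * m, -5, 5) * rbinom(m * m, 1, 0.4), m, m)
    u <- runif(m, 0, 5)
    x <- runif(m, 0, 1)
    p <- hill_params(W, u, 1, list(b1 = rep(0, m)))
    H <- hill_rhs(x, p) + x  # tau = 1, degradation 1: H = dx + x
    expect_true(all(H >= 0 & H < 1))
  }
})

test_that("simulation matches the closed-form linear solution", {
  # 1 gene, no edges, u = 1: H = 0.5, x(t) = 0.5 (1 - exp(-t))
  p <- hill_params(matrix(0, 1, 1), 1, 1, list(b1 = 0))
  tg <- seq(0, 5, by = 0.05)
  tr <- hill_simulate(p, 0, tg)
  expect_equal(unname(tr[1, ]), 0.5 * (1 - exp(-tg)), tolerance = 1e-5)
  # a fixed point stays fixed
  p0 <- hill_params(matrix(0, 1, 1), 0, 1, list(b1 = 0))
  expect_true(all(hill_simulate(p0, 0, tg) == 0))
})

test_that("simulation agrees with an independent deSolve integration", {
  ch <- two_gene_chain()
  tg <- seq(0, 2, by = 0.1)
  mine <- hill_simulate(ch$params, c(0.1, 0.1), tg)
  rhs <- function(t, x, parms) {
    W <- ch$params$W_in; u <- ch$params$u
    H <- vapply(1:2, function(i) {
      num <- u[i] + sum(pmax(W[, i], 0) * x^3)
      num / (1 + num + sum(pmax(-W[, i], 0) * x^3))
    }, 1)
    list((-x + H) / ch$params$tau)
  }
  ref <- deSolve::ode(c(0.1, 0.1), tg, rhs, NULL, method = "ode45",
                      rtol = 1e-8, atol = 1e-10)
  expect_equal(unname(mine), unname(t(ref[, -1])), tolerance = 1e-5)
})

test_that("trajectories never leave the unit box", {
  set.seed(11)
  for (rep in 1:25) {
    m <- sample(2:4, 1)
    W <- matrix(runif(m * m, -5, 5) * rbinom(m * m, 1, 0.5), m, m)
    p <- hill_params(W, runif(m, 0, 5), runif(1, 0.05, 5),
                     list(b1 = runif(m)))
    tr <- hill_simulate(p, p$x0_per_branch$b1, seq(0, 1, by = 0.02))
    expect_true(all(tr >= 0 & tr <= 1))
  }
})

test_that("knockdown modifies only the chosen gene's degradation", {
  ch <- two_gene_chain()
  tg <- seq(0, 2, by = 0.1)
  # k = 0 is a no-op
  expect_equal(knockdown_simulate(ch$params, knockdown_spec("g1", 0),
                                  c(0.1, 0.1), tg),
               hill_simulate(ch$params, c(0.1, 0.1), tg))
  # closed form: u = 1 gives H = 0.5; with k = 2 the equilibrium is 1/6
  p <- hill_params(matrix(0, 1, 1), 1, 1, list(b1 = 0))
  kd <- knockdown_simulate(p, knockdown_spec("g1", 2), 0,
                           seq(0, 40, by = 1))
  expect_equal(unname(kd[1, ncol(kd)]), 1 / 6, tolerance = 1e-5)
  expect_error(knockdown_simulate(p, knockdown_spec("gX", 2), 0, tg),
               "gX")
})

test_that("the composite loss decomposes as stated", {
  ch <- two_gene_chain()
  tg <- seq(0.05, 1, by = 0.05)
  traj <- hill_simulate(ch$params, c(0.1, 0.1), tg)
  ser <- list(binned_series("b1", tg, traj, rep(5, length(tg)),
                            ch$net$genes))
  cfg <- fit_config()
  lc <- hill_total_loss(ch$params, ser, cfg, ch$net)
  # the model reproduces its own data: only the L1 term remains
  expect_equal(unname(lc["L_model"]), 0, tolerance = 1e-10)
  expect_equal(unname(lc["L_IC"]), 0, tolerance = 1e-12)
  expect_equal(unname(lc["L_p"]), 3 + 1.5 + 0.3)
  expect_equal(unname(lc["L_total"]),
               unname(lc["L_model"] + cfg$lambda_p * lc["L_p"] +
                        cfg$lambda_ic * lc["L_IC"]),
               tolerance = 1e-9)
  # doubling lambda_ic doubles exactly the IC contribution
  p2 <- ch$params; p2$x0_per_branch$b1 <- c(0.3, 0.1)
  cfg2 <- fit_config(lambda_ic = 20)
  l1 <- hill_total_loss(p2, ser, fit_config(), ch$net)
  l2 <- hill_total_loss(p2, ser, cfg2, ch$net)
  expect_equal(unname(l2["L_total"] - l1["L_total"]),
               unname(10 * l1["L_IC"]), tolerance = 1e-9)
})

test_that("fitting respects the edge mask and is seed-reproducible", {
  ch <- two_gene_chain()
  tg <- seq(0.05, 1, by = 0.05)
  traj <- hill_simulate(ch$params, c(0.1, 0.1), tg)
  ser <- list(binned_series("b1", tg, traj, rep(5, length(tg)),
                            ch$net$genes))
  cfg <- fit_config(seed = 5, max_generations = 60)
  f1 <- hill_fit(ch$net, ser, cfg)
  f2 <- hill_fit(ch$net, ser, cfg)
  expect_identical(f1$loss_components, f2$loss_components)
  expect_identical(f1$params$W_in, f2$params$W_in)
  # off-edge entries are exactly zero
  expect_true(all(f1$params$W_in[adjacency(ch$net) == 0] == 0))
  expect_error(hill_fit(ch$net, list(), cfg), "empty")
})

test_that("stronger L1 regularisation does not increase the fitted L_p", {
  ch <- two_gene_chain()
  tg <- seq(0.05, 1, by = 0.05)
  traj <- hill_simulate(ch$params, c(0.1, 0.1), tg)
  ser <- list(binned_series("b1", tg, traj, rep(5, length(tg)),
                            ch$net$genes))
  f_lo <- hill_fit(ch$net, ser, fit_config(seed = 9, lambda_p = 0.001,
                                           max_generations = 150))
  f_hi <- hill_fit(ch$net, ser, fit_config(seed = 9, lambda_p = 0.1,
                                           max_generations = 150))
  expect_lte(f_hi$loss_components[["L_p"]],
             f_lo$loss_components[["L_p"]] + 1e-8)
})

test_that("fit classification distinguishes the outcome taxonomy", {
  genes <- paste0("g", 1:5)
  mkW <- function(w34, w35, wself = 3) {
    W <- matrix(0, 5, 5, dimnames = list(genes, genes))
    W["g3", "g4"] <- w34; W["g3", "g5"] <- w35
    W["g4", "g5"] <- -2; W["g5", "g4"] <- -2
    W["g4", "g4"] <- wself; W["g5", "g5"] <- wself
    W
  }
  x0a <- c(0, 0, 0, 0.05, 0.85)  # g5 branch
  x0b <- c(0, 0, 0, 0.85, 0.05)  # g4 branch
  u <- c(0, 0, 2, 0, 0)          # g3 held on by basal drive
  net <- gene_network(genes, which(mkW(1, 1) != 0, arr.ind = TRUE) |>
                        (\(ix) cbind(genes[ix[, 1]], genes[ix[, 2]]))())
  focus <- fit_focus("g3", "g5", "g4")
  mkfit <- function(W, x0s = list(b1 = x0a, b2 = x0b)) {
    structure(list(params = hill_params(W, u, 1, x0s, genes),
                   classification = NA_character_),
              class = "fit_result")
  }
  # restored edge dominant and knockdown lowers g5: mechanism recovered
  expect_equal(classify_fit(mkfit(mkW(0.1, 2, wself = 1.5)), net, focus),
               "mechanism_recovered")
  # competing arm dominant: damaged-like
  expect_equal(classify_fit(mkfit(mkW(2, 0)), net, focus),
               "damaged_like")
  # both arms decoupled from g3: basal drives explain the data
  expect_equal(classify_fit(mkfit(mkW(0.01, 0.01)), net, focus),
               "decoupled")
  # identical initial states collapse the branches
  expect_equal(classify_fit(mkfit(mkW(0.1, 2),
                                  x0s = list(b1 = x0a, b2 = x0a)),
                            net, focus),
               "no_bistability")
  expect_error(classify_fit(mkfit(mkW(1, 1)), net,
                            fit_focus("gX", "g5", "g4")), "gX")
})

test_that("fit results serialise to JSON and back", {
  ch <- two_gene_chain()
  tg <- seq(0.05, 1, by = 0.05)
  traj <- hill_simulate(ch$params, c(0.1, 0.1), tg)
  ser <- list(binned_series("b1", tg, traj, rep(5, length(tg)),
                            ch$net$genes))
  fit <- hill_fit(ch$net, ser, fit_config(seed = 5, max_generations = 30))
  f <- tempfile(fileext = ".json")
  write_fit_json(fit, f)
  back <- read_fit_json(f)
  expect_equal(back$params$W_in, fit$params$W_in)
  expect_equal(back$params$tau, fit$params$tau)
  expect_equal(back$loss_components, fit$loss_components)
})
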