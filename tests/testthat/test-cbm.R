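toy_default <- gen_toy_model()

test_that("media conversion turns concentrations into uptake bounds", {
  model <- toy_default$model
  media <- media_definition(quantitative = c(EX_arg = 1),
                            qualitative = "EX_ac",
                            biomass_density = 0.01, duration = 10)
  bounded <- media_to_bounds(model, media)
  rx <- bounded$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_arg"], -10)   # 1 / (0.01 * 10)
  expect_equal(rx$lower_bound[rx$id == "EX_ac"], -1)     # qualitative default
  # unlisted exchanges closed to uptake, secretion open
  expect_equal(rx$lower_bound[rx$id == "EX_orn"], 0)
  expect_equal(rx$upper_bound[rx$id == "EX_orn"], 1000)

  expect_error(media_definition(c(EX_arg = 1), biomass_density = 0,
                                duration = 10), "biomass_density")
  expect_error(media_definition(c(EX_arg = 0), biomass_density = 1,
                                duration = 1), "positive")
  media2 <- media_definition(c(EX_ghost = 1), biomass_density = 0.01,
                             duration = 10)
  expect_warning(media_to_bounds(model, media2), "EX_ghost")
})

test_that("FBA on the toy network matches the closed form over a bound grid", {
  for (A in c(1, 5, 10, 20)) {
    for (C in c(0.2, 1, 3)) {
      toy <- gen_toy_model(arg_uptake = A, ac_uptake = C)
      sol <- fba(toy$model)
      expect_equal(sol$mu, toy$closed_form(A, C), tolerance = 1e-6)
      # mass balance at the optimum
      expect_lt(max(abs(toy$model$S %*% sol$fluxes)), 1e-6)
    }
  }
  closed <- gen_toy_model(arg_uptake = 0, ac_uptake = 0)
  expect_equal(fba(closed$model)$mu, 0)
})

test_that("pFBA minimizes total flux and kills futile cycles", {
  model <- toy_default$model
  base <- fba(model)
  par <- pfba(model)
  expect_equal(par$mu, base$mu, tolerance = 1e-9)
  expect_equal(attr(par, "total_flux"), sum(abs(par$fluxes)))
  expect_lte(attr(par, "total_flux"), sum(abs(base$fluxes)) + 1e-9)

  # graft a two-reaction futile cycle onto an internal metabolite
  m2 <- model
  m2$metabolites <- rbind(m2$metabolites,
                          data.frame(id = "loop_c", name = "loop_c",
                                     compartment = "c"))
  m2$S <- rbind(m2$S, loop_c = 0)
  cyc <- matrix(0, nrow(m2$S), 2,
                dimnames = list(rownames(m2$S), c("CYC_F", "CYC_R")))
  cyc["co2_c", ] <- c(-1, 1)
  cyc["loop_c", ] <- c(1, -1)
  m2$S <- cbind(m2$S, cyc)
  m2$reactions <- rbind(m2$reactions,
                        data.frame(id = c("CYC_F", "CYC_R"),
                                   name = c("CYC_F", "CYC_R"),
                                   lower_bound = 0, upper_bound = 1000,
                                   gpr = "", subsystem = "",
                                   is_exchange = FALSE))
  par2 <- pfba(m2)
  expect_equal(unname(par2$fluxes[c("CYC_F", "CYC_R")]), c(0, 0),
               tolerance = 1e-9)
  expect_equal(par2$mu, base$mu, tolerance = 1e-9)
})

test_that("FVA brackets pFBA fluxes and pins the objective range", {
  model <- toy_default$model
  ranges <- fva(model, fraction = 0.99)
  par <- pfba(model)
  for (k in seq_len(nrow(ranges))) {
    v <- par$fluxes[[ranges$reaction[k]]]
    expect_gte(v, ranges$min_flux[k] - 1e-8)
    expect_lte(v, ranges$max_flux[k] + 1e-8)
  }
  ob <- ranges[ranges$reaction == "BIOMASS", ]
  mu <- fba(model)$mu
  expect_equal(ob$min_flux, 0.99 * mu, tolerance = 1e-9)
  expect_equal(ob$max_flux, mu, tolerance = 1e-9)
})

test_that("FVA matches an independent scipy per-reaction LP oracle", {
  model <- toy_default$model
  ranges <- fva(model, fraction = 0.99)
  oracle <- fva_oracle_scipy(model, fraction = 0.99)
  expect_equal(fba(model)$mu, oracle$mu, tolerance = 1e-8)
  expect_equal(ranges$min_flux, unname(oracle$ranges[ranges$reaction, "min"]),
               tolerance = 1e-7)
  expect_equal(ranges$max_flux, unname(oracle$ranges[ranges$reaction, "max"]),
               tolerance = 1e-7)
})

test_that("blocked reactions have zero FVA range and neutral knockouts", {
  model <- toy_default$model
  # add a reaction consuming a dead-end metabolite: stoichiometrically blocked
  m2 <- model
  m2$metabolites <- rbind(m2$metabolites,
                          data.frame(id = "dead_c", name = "dead_c",
                                     compartment = "c"))
  m2$S <- rbind(m2$S, dead_c = 0)
  blk <- matrix(0, nrow(m2$S), 1, dimnames = list(rownames(m2$S), "BLOCKED"))
  blk["dead_c", 1] <- -1
  blk["co2_c", 1] <- 1
  m2$S <- cbind(m2$S, blk)
  m2$reactions <- rbind(m2$reactions,
                        data.frame(id = "BLOCKED", name = "BLOCKED",
                                   lower_bound = 0, upper_bound = 1000,
                                   gpr = "", subsystem = "",
                                   is_exchange = FALSE))
  rng <- fva(m2, fraction = 1.0, reactions = "BLOCKED")
  expect_equal(c(rng$min_flux, rng$max_flux), c(0, 0), tolerance = 1e-9)
  kos <- single_reaction_knockouts(m2, reactions = "BLOCKED")
  expect_identical(kos$category, "neutral")
})

test_that("leave-one-out removal is monotone and respects redundancy", {
  toy <- gen_toy_model(variant = "agmatine", agm_uptake = 10)
  media <- media_definition(
    quantitative = c(EX_arg = 1, EX_ac = 0.1, EX_agm = 1),
    biomass_density = 0.01, duration = 10)
  bounded <- media_to_bounds(toy$model, media)
  full_mu <- fba(bounded)$mu
  loo <- simulate_leave_one_out(toy$model, media)
  expect_true(all(loo$mu <= full_mu + 1e-9))          # removal never helps
  # acetate is the sole precursor source: essential
  expect_false(loo$grows[loo$compound == "EX_ac"])
  # arginine and agmatine are redundant ATP sources at these bounds
  expect_equal(loo$mu[loo$compound == "EX_arg"], full_mu, tolerance = 1e-6)
  expect_equal(loo$mu[loo$compound == "EX_agm"], full_mu, tolerance = 1e-6)
})

test_that("growth confusion summary reproduces MCC arithmetic", {
  perfect <- growth_confusion(setNames(rep(c(TRUE, FALSE), each = 5), letters[1:10]),
                              setNames(rep(c(TRUE, FALSE), each = 5), letters[1:10]))
  expect_equal(perfect$mcc, 1)

  all_grow <- growth_confusion(setNames(rep(TRUE, 10), letters[1:10]),
                               setNames(rep(c(TRUE, FALSE), 5), letters[1:10]))
  expect_equal(all_grow$mcc, 0)

  pred <- setNames(rep(c(TRUE, FALSE), c(10, 5)), paste0("c", 1:15))
  obs <- setNames(c(rep(TRUE, 8), rep(FALSE, 2), TRUE, rep(FALSE, 4)),
                  paste0("c", 1:15))
  cs <- growth_confusion(pred, obs)
  expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(8, 2, 1, 4))
  expect_equal(cs$mcc, (8 * 4 - 2 * 1) / sqrt(10 * 9 * 6 * 5), tolerance = 1e-12)
  expect_equal(cs$fisher_p,
               fisher.test(matrix(c(8, 1, 2, 4), 2))$p.value)
  expect_error(growth_confusion(c(a = TRUE), c(b = TRUE)), "shared")
})

test_that("knockout screen categorizes essential and neutral reactions", {
  kos <- single_reaction_knockouts(toy_default$model)
  expect_identical(kos$category[kos$reaction == "BIOMASS"], "essential")
  expect_identical(kos$category[kos$reaction == "CK"], "essential")
  expect_true(all(kos$below_70pct[kos$category == "essential"]))

  # agmatine variant with both ATP routes open: ADI knockout only reduces
  toy2 <- gen_toy_model(arg_uptake = 5, ac_uptake = 1, variant = "agmatine",
                        agm_uptake = 5)
  kos2 <- single_reaction_knockouts(toy2$model)
  expect_identical(kos2$category[kos2$reaction == "ADI"], "reduced")
  expect_identical(kos2$category[kos2$reaction == "AGDI"], "reduced")
})

test_that("FVA-metabolomics concordance follows the direction rules", {
  rng <- data.frame(reaction = c("EX_a", "EX_b", "EX_c"),
                    min_flux = c(-5, 0, -5), max_flux = c(0, 3, 0),
                    fraction_of_optimum = 0.99)
  calls <- c(metA = "decreased", metB = "increased", metC = "increased")
  map <- c(metA = "EX_a", metB = "EX_b", metC = "EX_c", metD = "EX_d")
  out <- fva_exchange_concordance(rng, calls, map)
  v <- out$verdicts
  expect_true(v$compatible[v$metabolite == "metA"])    # import-only + decreased
  expect_true(v$compatible[v$metabolite == "metB"])    # secretable + increased
  expect_false(v$compatible[v$metabolite == "metC"])   # import-only + increased
  expect_equal(out$fraction_compatible, 2 / 3)
  out2 <- fva_exchange_concordance(rng, c(calls, metD = "increased"), map)
  expect_identical(out2$unmapped, "metD")
})

test_that("flux-expression concordance recovers rank agreement and the null", {
  # fabricated model: 500 exchange-style reactions, one gene each
  n <- 500
  mets <- data.frame(id = sprintf("m%03d", seq_len(n)))
  rxns <- data.frame(id = sprintf("r%03d", seq_len(n)), lower_bound = -10,
                     upper_bound = 10, gpr = sprintf("g%03d", seq_len(n)))
  S <- diag(n); dimnames(S) <- list(mets$id, rxns$id)
  model <- metabolic_model(mets, rxns, -S, objective = "r001")
  set.seed(31)
  flux <- setNames(c(rep(0, 250), runif(250, 0.1, 5)), rxns$id)
  sol <- structure(list(status = "optimal", mu = 1, fluxes = flux),
                   class = "flux_solution")
  expr_aligned <- setNames(rank(abs(flux)), sprintf("g%03d", seq_len(n)))
  out <- flux_expression_concordance(sol, expr_aligned, model)
  expect_gt(out$spearman_rho, 0.99)
  expect_equal(out$n_pairs, n)
  expect_gt(out$active_top_half_frac, out$inactive_top_half_frac)

  null_hits <- replicate(40, {
    ex <- setNames(sample(expr_aligned), names(expr_aligned))
    abs(flux_expression_concordance(sol, ex, model)$spearman_rho) < 0.1
  })
  expect_gte(mean(null_hits), 0.95)

  all_active <- structure(list(status = "optimal", mu = 1,
                               fluxes = setNames(runif(n, 1, 2), rxns$id)),
                          class = "flux_solution")
  expect_equal(flux_expression_concordance(all_active, expr_aligned,
                                           model)$ratio, 1)
  expect_error(flux_expression_concordance(sol, c(zz = 1), model), "10")
})

test_that("knockout-conservation test separates planted gene classes", {
  n <- 100
  mets <- data.frame(id = sprintf("m%03d", 1:n))
  rxns <- data.frame(id = sprintf("r%03d", 1:n), lower_bound = -10,
                     upper_bound = 10, gpr = sprintf("g%03d", 1:n))
  S <- -diag(n); dimnames(S) <- list(mets$id, rxns$id)
  model <- metabolic_model(mets, rxns, S, objective = "r001")
  kos <- data.frame(reaction = rxns$id, mu_ko = c(rep(0, 50), rep(1, 50)),
                    category = "x", below_70pct = c(rep(TRUE, 50), rep(FALSE, 50)))
  set.seed(13)
  presence <- setNames(c(rep(1, 50), runif(50, 0.3, 0.7)), sprintf("g%03d", 1:n))
  core <- presence == 1
  out <- knockout_conservation_test(kos, model, presence, core)
  expect_lt(out$wilcoxon_p, 0.01)
  expect_gt(out$fisher_or, 1)

  same <- setNames(rep(0.5, n), sprintf("g%03d", 1:n))
  out2 <- knockout_conservation_test(kos, model, same, setNames(rep(TRUE, n), names(same)))
  expect_gt(out2$wilcoxon_p, 0.99)
  expect_false(is.null(out2$note))

  kos_all <- kos; kos_all$below_70pct <- TRUE
  expect_error(knockout_conservation_test(kos_all, model, presence, core),
               "partition")
})
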