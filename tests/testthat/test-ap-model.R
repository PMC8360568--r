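test_that("model construction validates the parameter file", {
  m <- build_ap_model(cell_type = "adult-human", mutation = "WT")
  expect_s3_class(m, "ap_model")
  expect_identical(m$mutation, "WT")
  expect_true(all(model_rho(m) >= 0))

  # a file missing one rho entry is rejected with a pointed message
  raw <- yaml::read_yaml(surrogate_model_path())
  raw$currents$I_f$rho$rabbit <- NULL
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, bad)
  expect_error(build_ap_model(bad, cell_type = "rabbit"), "I_f")

  raw2 <- yaml::read_yaml(surrogate_model_path())
  names(raw2$currents)[1] <- "I_bogus"
  bad2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw2, bad2)
  expect_error(build_ap_model(bad2), "current_id")
})

test_that("mutation and maturation act on orthogonal model components", {
  wt <- build_ap_model(cell_type = "adult-human", mutation = "WT")
  mut <- set_mutation(wt, "N588K")
  # same densities, different gate variant only
  expect_identical(model_rho(wt), model_rho(mut))
  expect_identical(wt$g0, mut$g0)

  # frozen pseudo-random states: current ratios across cell types are
  # mutation-independent, and mutant/WT ratios are cell-type-independent
  set.seed(42)
  for (rep in 1:5) {
    state <- c(v = runif(1, -90, 40), m = runif(1), h = runif(1), j = runif(1),
               hL = runif(1), d = runif(1), f = runif(1), xr1 = runif(1),
               xs = runif(1), s = runif(1), y = runif(1),
               cai = runif(1, 1e-4, 1e-3), casr = runif(1, 0.5, 2))
    currents <- lapply(c("adult-human", "hiPSC-CM"), function(ct)
      lapply(c("WT", "N588K"), function(mu)
        eval_currents(set_mutation(translate_cell_type(wt, ct), mu), state)))
    adult_wt <- currents[[1]][[1]]; adult_mut <- currents[[1]][[2]]
    ipsc_wt <- currents[[2]][[1]]; ipsc_mut <- currents[[2]][[2]]
    nonzero <- abs(adult_wt) > 1e-12 & abs(ipsc_wt) > 1e-12
    # maturation ratio is the same with and without the mutation
    expect_equal((ipsc_wt / adult_wt)[nonzero],
                 (ipsc_mut / adult_mut)[nonzero], tolerance = 1e-12)
    # mutation ratio is the same in both cell types (only I_Kr changes at all)
    expect_equal((adult_mut / adult_wt)[nonzero],
                 (ipsc_mut / ipsc_wt)[nonzero], tolerance = 1e-12)
    changed <- names(which(abs(adult_mut - adult_wt) > 1e-12))
    expect_true(all(changed %in% "I_Kr"))
  }
})

test_that("cell-type translation rescales currents by the density ratio", {
  m_ipsc <- build_ap_model(cell_type = "hiPSC-CM", mutation = "N588K")
  m_adult <- translate_cell_type(m_ipsc, "adult-human")
  expect_identical(m_adult$mutation, "N588K")  # mutation carried over
  expect_identical(m_adult$g0, m_ipsc$g0)      # flux untouched
  expect_identical(translate_cell_type(m_adult, "adult-human"), m_adult)

  state <- m_ipsc$initial_state
  i_ipsc <- eval_currents(m_ipsc, state)
  i_adult <- eval_currents(m_adult, state)
  ratio <- model_rho(m_adult) / model_rho(m_ipsc)
  nz <- abs(i_ipsc) > 1e-12
  expect_equal(unname((i_adult / i_ipsc)[nz]), unname(ratio[nz]),
               tolerance = 1e-12)
})

test_that("drug factors are independent of cell type and density profile", {
  lib <- default_drug_library()
  doses <- c(disopyramide = 5, veratridine = 0.4)
  m1 <- build_ap_model(cell_type = "adult-human", mutation = "N588K")
  m2 <- translate_cell_type(m1, "rabbit")
  expect_identical(model_factors(m1, lib, doses), model_factors(m2, lib, doses))
  expect_identical(model_factors(m1, lib, doses),
                   model_factors(set_mutation(m1, "WT"), lib, doses))
})

test_that("ohmic fluxes vanish at their reversal potentials", {
  m <- build_ap_model()
  base <- m$initial_state
  state_at <- function(v) { s <- base; s[["v"]] <- v; s }
  iK <- eval_currents(m, state_at(m$constants[["E_K"]]))
  expect_equal(unname(iK[c("I_Kr", "I_Ks", "I_K1", "I_to")]), rep(0, 4))
  iNa <- eval_currents(m, state_at(m$constants[["E_Na"]]))
  expect_equal(unname(iNa[c("I_Na", "I_NaL")]), rep(0, 2))
  expect_equal(unname(eval_currents(m, state_at(m$constants[["E_CaL"]]))[["I_CaL"]]), 0)
})

test_that("compiled and R current evaluations agree at the end of a beat", {
  proto <- fast_protocol(n_prebeats = 3)
  for (ct in c("adult-human", "hiPSC-CM")) {
    m <- build_ap_model(cell_type = ct, mutation = "N588K")
    tr <- simulate_ap(m, protocol = proto, include_currents = TRUE)
    last <- nrow(tr)
    r_side <- eval_currents(m, attr(tr, "final_state"))
    c_side <- unlist(tr[last, names(r_side)])
    expect_equal(unname(c_side), unname(r_side), tolerance = 1e-8)
  }
})

test_that("unit drug factors reproduce the drug-free solution bitwise", {
  m <- build_ap_model(mutation = "N588K")
  proto <- fast_protocol(n_prebeats = 3)
  plain <- simulate_ap(m, protocol = proto)
  unit <- simulate_ap(m, factors = stats::setNames(rep(1, 12),
                                                   names(model_rho(m))),
                      protocol = proto)
  expect_identical(plain$v, unit$v)
  expect_identical(plain$ca, unit$ca)
})

test_that("with all conductances zeroed and no stimulus the potential is frozen", {
  m <- build_ap_model()
  proto <- pacing_protocol(stimulus_amplitude = 0, n_prebeats = 1,
                           dt_output = 0.5)
  factors <- stats::setNames(rep(0, 12), names(model_rho(m)))
  tr <- simulate_ap(m, factors = factors, protocol = proto)
  expect_lt(diff(range(tr$v)), 1e-6)
})

test_that("the mutant beat is shorter with a depressed calcium transient", {
  proto <- fast_protocol()
  wt <- compute_biomarkers(simulate_ap(build_ap_model(mutation = "WT"),
                                       protocol = proto))
  mut <- compute_biomarkers(simulate_ap(build_ap_model(mutation = "N588K"),
                                        protocol = proto))
  expect_lt(mut[["APD90"]], wt[["APD90"]])
  expect_lt(mut[["APD50"]], wt[["APD50"]])
  expect_lt(mut[["CaA"]], wt[["CaA"]])
})

test_that("refining integrator tolerances leaves APD90 stable", {
  m <- build_ap_model(mutation = "WT")
  proto <- fast_protocol(n_prebeats = 5)
  a <- compute_biomarkers(simulate_ap(m, protocol = proto, rtol = 1e-6))
  b <- compute_biomarkers(simulate_ap(m, protocol = proto, rtol = 1e-7))
  expect_lt(abs(a[["APD90"]] - b[["APD90"]]), 0.5)
})

test_that("trace export and re-import round-trips the waveform", {
  m <- build_ap_model()
  tr <- simulate_ap(m, protocol = fast_protocol(n_prebeats = 2),
                    include_currents = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_trace(tr, path)
  header <- readLines(path, n = 1)
  expect_match(header, "^time_ms\tv_mV\tca_uM")
  back <- read_trace(path)
  expect_equal(back$v, tr$v, tolerance = 1e-6)
  expect_equal(back$ca, tr$ca, tolerance = 1e-6)
  expect_true(all(diff(back$time) > 0))
})
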