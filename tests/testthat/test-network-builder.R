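# Species enumeration, reaction generation, mass balance, serialization.

test_that("species enumeration matches the combinatorial counts", {
  # 36 free conformers + 9 each for the three RR-binders + 18 Ng-bound
  # + 5 CaN loading states + free CaMKII/CaMKIIp/Ng/Ca
  expect_equal(nrow(enumerate_species(model_config())), 90)
  expect_equal(nrow(enumerate_species(model_config(with_ng = FALSE))),
               90 - 18 - 1)
  expect_equal(nrow(enumerate_species(model_config(
    with_camkii = FALSE, with_can = FALSE, with_ng = FALSE,
    phospho = FALSE))), 36 + 1)
  expect_error(model_config(with_camkii = FALSE, phospho = TRUE),
               "configuration error")
})

test_that("calmodulin-only reaction count matches a brute-force enumeration", {
  net <- cam_only_network_closed()
  # independent oracle: loop over all explicit (conf, occupancy) states
  n_bind <- 0; n_trans <- 0
  for (cN in c("T", "R")) for (nN in 0:2) for (cC in c("T", "R")) for (nC in 0:2) {
    if (nN < 2) n_bind <- n_bind + 2   # bind + unbind on the N lobe
    if (nC < 2) n_bind <- n_bind + 2
    if (cN == "T") n_trans <- n_trans + 2  # open + close, counted from T side
    if (cC == "T") n_trans <- n_trans + 2
  }
  expect_equal(nrow(net$reactions), n_bind + n_trans)
  expect_equal(nrow(net$reactions), 168)
})

test_that("partner affinity is independent of calcium occupancy", {
  net <- full_network()
  rr <- net$reactions
  sp <- net$species
  id_at <- function(i) ifelse(i > 0, sp$id[pmax(i, 1)], "")
  on <- rr[rr$kind == "partner_on" & id_at(rr$r2) == "CaMKII", ]
  off <- rr[rr$kind == "partner_off" & id_at(rr$p2) == "CaMKII", ]
  expect_equal(nrow(on), 9)   # one per RR occupancy combination
  kd <- off$k[match(off$r1, on$p1)] / on$k
  expect_equal(kd, rep(1.1 / 2.87e6, 9))
  expect_equal(kd[1], 3.8e-7, tolerance = 0.01)
})

test_that("every reaction is mass balanced and knock-outs are subsets", {
  net <- full_network()
  expect_true(check_mass_balance(net))
  ko <- build_network(config = model_config(with_ng = FALSE))
  key <- function(n) {
    id <- function(i) ifelse(i > 0, n$species$id[pmax(i, 1)], "-")
    with(n$reactions, paste(kind, k, id(r1), id(r2), id(p1), id(p2)))
  }
  expect_true(all(key(ko) %in% key(net)))
  expect_equal(nrow(ko$reactions),
               nrow(net$reactions) - sum(grepl("Ng", key(net))))
})

test_that("detailed balance holds exactly and detects a rounded off-rate", {
  net <- full_network()
  db <- validate_detailed_balance(net)
  expect_gt(db$n_cycles, 0)
  expect_lt(db$max_log_ratio, 1e-9)
  # perturbation: replace the C-lobe open-state calcium off-rate with the
  # rounded 0.6 /s and the cycles no longer close
  pert <- net
  koffCR <- 1.22e8 * 9.38e-5 * 5e-5
  hit <- pert$reactions$kind == "ca_unbind" &
    abs(pert$reactions$k / koffCR - round(pert$reactions$k / koffCR)) < 1e-9 &
    pert$reactions$k < 2.5 * koffCR
  expect_gt(sum(hit), 0)
  pert$reactions$k[hit] <- 0.6 * round(pert$reactions$k[hit] / koffCR)
  expect_gt(validate_detailed_balance(pert)$max_log_ratio, 1e-3)
})

test_that("the pump/leak subsystem settles at the closed-form basal calcium", {
  cfg <- model_config()
  closed_form <- cfg$leak * cfg$pump_Km / (cfg$pump_Vmax - cfg$leak)
  expect_equal(closed_form, 8.0e-8, tolerance = 2e-3)
  eq <- full_equilibrium()
  expect_equal(eq$state[["Ca"]], closed_form, tolerance = 1e-6)
})

test_that("SBML export round-trips to an identical right-hand side", {
  net <- full_network()
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(net, path)
  doc <- xml2::read_xml(path)  # well-formed XML with SBML structure
  expect_equal(xml2::xml_name(doc), "sbml")
  imp <- import_sbml(path)
  expect_equal(nrow(imp$species), 90)
  expect_equal(imp$species$id, net$species$id)
  set.seed(42)
  y <- stats::runif(90) * 1e-6
  expect_equal(network_rhs(imp, y), network_rhs(net, y), tolerance = 1e-12)
})

test_that("an empty network exports a compartment-only document", {
  empty <- structure(list(
    species = data.frame(id = character(0), init = numeric(0)),
    reactions = data.frame(kind = character(0), k = numeric(0),
                           r1 = integer(0), r2 = integer(0),
                           p1 = integer(0), p2 = integer(0)),
    special = NULL, config = list(volume = 1e-15)),
    class = "reaction_network")
  path <- withr::local_tempfile(fileext = ".xml")
  expect_no_error(export_sbml(empty, path))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, ".//compartment"), 1)
  expect_length(xml2::xml_find_all(doc, ".//listOfSpecies/species"), 0)
})

test_that("compiled and reference right-hand sides agree", {
  net <- full_network()
  hemicam:::use_network(net, influx = 0)
  set.seed(7)
  for (i in 1:5) {
    y <- stats::runif(90) * 10^stats::runif(1, -8, -4)
    expect_equal(hemicam:::compiled_rhs(y), network_rhs(net, y),
                 tolerance = 1e-14)
  }
})

test_that("YAML configuration reproduces the built-in defaults", {
  path <- system.file("extdata", "reference_params.yaml", package = "hemicam")
  m <- read_model_yaml(path)
  expect_equal(unclass(m$params), unclass(cam_params()))
  expect_equal(unclass(m$partners), unclass(partner_params()))
  expect_equal(m$config$CaM, 4e-5)
  net1 <- build_network(m$params, m$partners, m$config)
  net2 <- full_network()
  expect_equal(net1$reactions$k, net2$reactions$k)
})
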