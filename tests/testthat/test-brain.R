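test_that("the default brain has five regions and the required pathways", {
  brain <- cached("brain1", build_brain(seed = 1))
  expect_setequal(names(brain$areas),
                  c("ACC", "BA9", "BA10", "BA46", "preSMA"))
  tab <- projection_table(brain)
  expect_gte(nrow(tab), 8)
  expect_true(all(c("BA9", "BA10", "BA46") %in%
                    tab$target[tab$source == "ACC"]))
  expect_true(all(c("BA10", "BA9") %in% tab$source[tab$target == "preSMA"]))
  # BA9 <-> BA10 <-> BA46 bidirectional
  for (pair in list(c("BA9", "BA10"), c("BA10", "BA46"), c("BA9", "BA46"))) {
    expect_true(any(tab$source == pair[1] & tab$target == pair[2]))
    expect_true(any(tab$source == pair[2] & tab$target == pair[1]))
  }
})

test_that("a config without ACC is rejected", {
  cfg <- default_brain_config()
  cfg$areas$ACC <- NULL
  expect_error(build_brain(cfg), "exactly the areas")
  cfg2 <- default_brain_config()
  cfg2$bogus <- 1
  expect_error(build_brain(cfg2), "unknown config keys")
})

test_that("brain construction is deterministic given the seed", {
  a <- build_brain(seed = 7)
  b <- build_brain(seed = 7)
  expect_identical(a$net$con, b$net$con)
})

test_that("no projection terminates on the feedback-inhibitory layer and no cross-area I-I exists", {
  brain <- cached("brain1", build_brain(seed = 1))
  con <- brain$net$con
  proj <- con[grepl("^proj_", con$class), ]
  tgt_layer <- brain$net$layer[proj$i]
  expect_true(all(tgt_layer %in% c("E", "FF")))
  # long-range projections originate from excitatory units only
  expect_true(all(brain$net$layer[proj$j] == "E"))
  # globally: never inhibitory -> inhibitory
  inh_src <- brain$net$layer[con$j] != "E"
  inh_tgt <- brain$net$layer[con$i] != "E"
  expect_false(any(inh_src & inh_tgt))
})

test_that("brain_units resolves areas, layers and assemblies consistently", {
  brain <- cached("brain1", build_brain(seed = 1))
  e10 <- brain_units(brain, "BA10")
  expect_length(e10, 100)
  expect_true(all(brain$net$layer[e10] == "E"))
  a1 <- brain_units(brain, "BA10", assembly = 1)
  expect_true(all(a1 %in% e10))
  expect_error(brain_units(brain, "preSMA"), "readout")
})

test_that("each area's excitatory mean stays bounded over a long run", {
  brain <- cached("brain1", build_brain(seed = 1))
  probes <- lapply(c(ACC = "ACC", BA9 = "BA9", BA10 = "BA10", BA46 = "BA46"),
                   function(a) brain_units(brain, a))
  out <- run_net(brain$net, duration = 4000, dt = 0.1, seed = 2,
                 probes = probes)
  for (a in names(probes)) {
    x <- out$ts$channels[[a]]
    x <- x[-seq_len(length(x) / 4)]
    expect_lt(max(abs(x - mean(x))), 10 * max(sd(x), 0.1))
    expect_lt(abs(mean(x)), 10)   # no runaway excitation
  }
})
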