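test_that("the position map reproduces the printed backbone positions", {
  pm <- compute_position_map(11, amino_acid_carbons = 2)
  expect_identical(pm$alpha[pm$e == 11], 2L)    # final elongation -> Delta-2 alpha
  expect_identical(pm$beta[pm$e == 3], 19L)     # macrolactonisation hydroxyl
  expect_identical(pm$beta[pm$e == 9], 7L)
  expect_identical(pm$beta[pm$e == 4], 17L)
  expect_identical(pm$alpha[pm$e == 7], 10L)
  expect_identical(pm$alpha[pm$e == 5], 14L)
  expect_identical(pm$beta[pm$e == 1], 2L * 11L + 1L)
  expect_error(compute_position_map(0), ">= 1")
})

test_that("the position map matches a brute-force chain walk and is bijective", {
  for (E in c(1, 2, 5, 8)) {
    pm <- compute_position_map(E)
    # walk the finished chain from the thioester end: unit E contributes
    # C1 (carbonyl) and C2 (alpha), unit E-1 the next pair, and so on; the
    # beta carbon of unit e is the first carbon of the next pair upstream
    walk <- rev(rep(seq_len(E), each = 2))    # unit owning each position
    for (e in seq_len(E)) {
      owned <- which(walk == e)
      expect_identical(pm$alpha[pm$e == e], owned[2])
      expect_identical(pm$beta[pm$e == e], owned[2] + 1L)
    }
    expect_identical(sort(c(pm$alpha, pm$alpha - 1L)), seq_len(2L * E))
  }
})

test_that("chain initialisation records starter and amino-acid contributions", {
  ch <- initialize_chain("3-methylcrotonic_acid", "glycine")
  expect_true(ch$open)
  expect_length(ch$units, 0)
  expect_identical(ch$starter$carbon_count, 5L)
  expect_identical(ch$amino_acids[[1]]$backbone_carbons, 2L)
  expect_identical(ch$amino_acids[[1]]$nitrogens, 1L)
  expect_false(ch$starter$terminal_olefin)

  expect_true(initialize_chain("3-methyl-3-butenoic_acid")$starter$terminal_olefin)
  expect_error(initialize_chain("foo"), "unknown starter")
})

test_that("elongation beta-state rules follow the module domain set", {
  mk <- function(...) list(index = 9L, role = "pks_elongation",
                           domains = c(list(domain("KS")), list(...),
                                       list(domain("ACP"))),
                           elongation_ordinal = 1L,
                           trans_annotations = character(0))
  ch <- initialize_chain("acetate", "glycine")
  u <- function(module, ...) {
    tail(apply_elongation(ch, module, ...)$units, 1)[[1]]
  }
  expect_identical(u(mk())$beta_state, "ketone")
  expect_identical(u(mk(domain("KR", kr_type = "A")))$beta_state, "hydroxyl_L")
  expect_identical(u(mk(domain("KR", kr_type = "B")))$beta_state, "hydroxyl_D")
  expect_identical(u(mk(domain("KR", kr_type = "C")))$beta_state, "ketone")

  cis <- u(mk(domain("KR", kr_type = "A"), domain("DH")))
  expect_identical(cis$beta_state, "olefin")
  expect_identical(cis$geometry, "cis")
  trans <- u(mk(domain("KR", kr_type = "B"), domain("DH")))
  expect_identical(trans$geometry, "trans")

  # module 9 pattern: B-type KR plus LLM -> D-hydroxyl at beta, hydroxyl at alpha
  m9 <- u(mk(domain("KR", kr_type = "B"), domain("LLM")))
  expect_identical(m9$beta_state, "hydroxyl_D")
  expect_true(m9$alpha_hydroxyl)

  # module 3 pattern: DH + cMT without KR, permissive -> shifted olefin + methyl
  m3 <- u(mk(domain("DH", shift = TRUE), domain("cMT")))
  expect_identical(m3$beta_state, "olefin_shifted")
  expect_true(m3$alpha_methyl)
  strict <- u(mk(domain("DH", shift = TRUE), domain("cMT")), permissive_dh = FALSE)
  expect_identical(strict$beta_state, "ketone")

  # module 8 pattern: KR + DH with a trans-acting ER -> fully saturated
  m8 <- mk(domain("DH"), domain("KR", kr_type = "B"))
  m8$trans_annotations <- "trans_ER"
  expect_identical(u(m8)$beta_state, "saturated")

  closed <- ch
  closed$open <- FALSE
  expect_error(apply_elongation(closed, mk()), "closed")
  bad <- mk()
  bad$role <- "loading"
  expect_error(apply_elongation(ch, bad), "not an elongation")
})

test_that("beta-branching needs an hcs-flagged ketone and a complete cassette", {
  arch <- pal_arch(4)
  ch <- initialize_chain("3-methylcrotonic_acid", "glycine")
  roles <- vapply(arch$modules, `[[`, character(1), "role")
  for (m in arch$modules[roles == "pks_elongation"]) ch <- apply_elongation(ch, m)
  cassette <- detect_hcs_cassette(arch)
  expect_true(cassette$hcs && cassette$free_ks)
  expect_identical(cassette$n_ech, 2L)

  ch2 <- apply_beta_branch(ch, cassette, 4)   # module 6 unit
  expect_true(ch2$units[[4]]$branch$internal_olefin)

  expect_error(apply_beta_branch(ch, cassette, 3), "substrate error")
  incomplete <- cassette
  incomplete$hcs <- FALSE
  expect_error(apply_beta_branch(ch, incomplete, 4), "incomplete")
})

test_that("auto macrolactonisation selects C-19; all-ketone chains stay linear", {
  s4 <- suppressWarnings(assemble(pal_arch(4)))
  expect_identical(s4$ring, c(from = 1L, to = 19L))

  ketone_only <- toy_arch(rep(list(list(domain("KS"))), 6))
  expect_warning(st <- assemble(ketone_only), "linear")
  expect_null(st$ring)
})

test_that("a termination domain without the catalytic histidine refuses release", {
  arch <- pal_arch(4)
  term <- which(vapply(arch$modules, `[[`, character(1), "role") == "termination")
  arch$modules[[term]]$domains[[1]]$active <- FALSE
  expect_error(assemble(arch), "catalytic histidine")
})

test_that("tailoring decorates free hydroxyls once and only once", {
  st <- assemble(pal_arch(4), run_tailoring = FALSE)
  dec <- apply_tailoring(st, list(list(enzyme = "CT", target = 11)))
  expect_identical(dec$table$decoration[11], "carbamate")

  # palmerolide B pattern: carbamate moved to C-7, sulfate on C-11
  b <- apply_tailoring(st, list(list(enzyme = "CT", target = 7),
                                list(enzyme = "sulfotransferase", target = 11)))
  expect_identical(b$table$decoration[7], "carbamate")
  expect_identical(b$table$decoration[11], "sulfate")

  expect_error(apply_tailoring(st, list(list(enzyme = "CT", target = 3))),
               "lacks a hydroxyl")
  # targets are consumed: double decoration is an error
  expect_error(apply_tailoring(dec, list(list(enzyme = "CT", target = 11))),
               "already consumed")
})

test_that("pal BGC 4 assembles to the palmerolide A feature set", {
  st <- assemble(pal_arch(4))
  expect_identical(st$E, 11L)
  expect_identical(st$polyketide_carbon_count, 22L)
  expect_identical(st$backbone_carbon_count, 24L)
  expect_identical(st$total_carbon_count, 32L)

  ole <- olefin_positions(st)
  expect_identical(ole$delta, c(2L, 8L, 14L, 16L, 21L, 23L))
  expect_identical(ole$geometry[ole$delta %in% c(2, 8, 14)], rep("trans", 3))
  expect_identical(ole$geometry[ole$delta %in% c(21, 23)], rep("trans", 2))

  oh <- hydroxyl_positions(st)
  expect_identical(oh$position, c(7L, 10L, 11L, 19L))
  expect_identical(oh$stereo[oh$position == 7], "D")
  expect_true(is.na(oh$stereo[oh$position == 10]))          # alpha-hydroxyl
  expect_identical(oh$decoration[oh$position == 11], "carbamate")

  expect_true(st$table$branch[17])
  expect_true(st$table$branch_internal_olefin[17])
  # substituent methyls numbered beyond the backbone by host position
  expect_identical(st$table$branch_carbon[17], 25L)
  expect_identical(st$table$methyl_carbon[20], 26L)
  expect_identical(st$table$methyl_carbon[22], 27L)
})

test_that("the starter-extension module of pal BGC 1 stays off the numbered backbone", {
  st <- assemble(pal_arch(1))
  expect_identical(st$E, 11L)
  expect_identical(st$tail_extension, 1L)
  expect_identical(st$tail_methyls, 1L)
  expect_identical(st$backbone_carbon_count, 24L)
  expect_identical(st$total_carbon_count, 35L)   # 32 + CH2-CH(CH3) extension
})

test_that("carbon conservation and olefin-geometry invariants hold over simulations", {
  for (s in 1:60) {
    sim <- simulate_architecture(sim_config(s))
    st <- suppressWarnings(assemble(sim$arch))
    n_methyl <- sum(st$table$methyl)
    n_branch <- sum(st$table$branch)
    starter_c <- if (is.null(st$starter)) 0L else st$starter$carbon_count
    aa_c <- 2L * length(st$amino_acids)
    expect_identical(st$total_carbon_count,
                     starter_c + 2L * st$E + aa_c + n_methyl + n_branch)
    # geometry rule: A-type KR + DH -> cis, B-type + DH -> trans
    roles <- vapply(sim$arch$modules, `[[`, character(1), "role")
    emods <- sim$arch$modules[roles == "pks_elongation"]
    for (u in seq_len(nrow(st$units))) {
      row <- st$units[u, ]
      if (row$beta_state %in% c("olefin", "olefin_shifted")) {
        m <- emods[[row$e]]
        kr <- NULL
        for (d in m$domains) if (d$kind == "KR" && d$kr_type %in% c("A", "B")) kr <- d
        if (!is.null(kr) && !is.na(row$olefin_position)) {
          geom <- st$table$geometry[row$olefin_position]
          expect_identical(geom, if (kr$kr_type == "A") "cis" else "trans")
        }
      }
    }
  }
})
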