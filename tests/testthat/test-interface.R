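test_that("salt-bridge detection distinguishes side-chain and backbone-oxygen kinds", {
  fx <- gen_complex_fixture(c("salt_bridge", "salt_bridge_backbone"),
                            seed = 2, bridge_distance = 3.0)
  sb <- detect_salt_bridges(fx$model, "A", "B")
  expect_same_bridges(sb, fx$ground_truth$salt_bridges)
  expect_true(all(abs(sb$min_distance - 3.0) < 0.2))   # jitter-sized slack
  expect_true(all(sb$min_distance <= 4.0))
  # beyond the cutoff: nothing
  far <- gen_complex_fixture("salt_bridge", seed = 2, bridge_distance = 6.0)
  expect_equal(nrow(detect_salt_bridges(far$model, "A", "B")), 0L)
  # symmetric in chain order modulo role fields
  ba <- detect_salt_bridges(fx$model, "B", "A")
  expect_equal(nrow(ba), nrow(sb))
  expect_equal(sort(ba$basic_res_seq), sort(sb$basic_res_seq))
  expect_equal(sort(ba$kind), sort(sb$kind))
})

test_that("beta-ladder detection recovers registry and orientation; helices give none", {
  fx <- gen_complex_fixture(c("beta_antiparallel", "beta_parallel"),
                            seed = 3, beta_length = 6)
  bp <- detect_interchain_beta_pairs(fx$model, "A", "B")
  expect_same_pairings(bp, fx$ground_truth$pairings)
  expect_true(all(vapply(bp, function(p) nrow(p$registry) >= 2L, logical(1))))

  hel <- gen_complex_fixture("helix_contact", seed = 3)
  expect_equal(length(detect_interchain_beta_pairs(hel$model, "A", "B")), 0L)
  # inter-chain only: same chain for both arguments is empty by contract
  expect_equal(length(detect_interchain_beta_pairs(fx$model, "A", "A")), 0L)
})

test_that("insertion calls require a receptor: burial is 0 without the partner chain", {
  fx <- gen_complex_fixture("insertion", seed = 5)
  rs <- fx$ground_truth$insertions$res_seq[1]
  b <- delta_sasa_insertion(fx$model, "B", "A", rs)
  expect_true(b$inserted)
  expect_gte(b$relative_burial, 0.7)
  # strip the receptor: client alone buries nothing
  alone <- structure_model(fx$model$atoms[fx$model$atoms$chain == "B", ])
  b0 <- delta_sasa_insertion(alone, "B", "A", rs)
  expect_equal(b0$relative_burial, 0)
  expect_false(b0$inserted)
  # a residue far from any interface stays essentially unburied
  fx2 <- gen_complex_fixture(c("insertion", "apart"), seed = 5)
  apart_res <- max(chain_residues(fx2$model, "B")$res_seq)
  b1 <- delta_sasa_insertion(fx2$model, "B", "A", apart_res)
  expect_lt(b1$relative_burial, 0.05)
  # glycine: flagged C-alpha proxy rather than an error
  expect_true(b1$gly_proxy)
  expect_error(delta_sasa_insertion(fx$model, "B", "A", 999), "not on chain")
})

test_that("detectors are invariant under rigid-body isometries", {
  fx <- gen_complex_fixture(c("salt_bridge", "beta_antiparallel", "insertion"),
                            seed = 11)
  sb0 <- detect_salt_bridges(fx$model, "A", "B")
  bp0 <- detect_interchain_beta_pairs(fx$model, "A", "B")
  rs <- fx$ground_truth$insertions$res_seq[1]
  ins0 <- delta_sasa_insertion(fx$model, "B", "A", rs)
  set.seed(99)
  for (k in 1:5) {
    m <- random_isometry(fx$model)
    sb <- detect_salt_bridges(m, "A", "B")
    expect_equal(sb[, names(sb) != "min_distance"],
                 sb0[, names(sb0) != "min_distance"])
    expect_lt(max(abs(sb$min_distance - sb0$min_distance)), 1e-9)
    expect_same_pairings(detect_interchain_beta_pairs(m, "A", "B"), bp0)
    ins <- delta_sasa_insertion(m, "B", "A", rs)
    expect_equal(ins$inserted, ins0$inserted)
    # SASA sampling is lattice-fixed: rotation changes areas only within
    # sampling error
    expect_lt(abs(ins$relative_burial - ins0$relative_burial), 0.05)
  }
})

test_that("interface report aggregates exactly the planted features", {
  fx <- gen_complex_fixture(c("salt_bridge", "beta_antiparallel", "insertion"),
                            seed = 21)
  rep <- interface_report(fx$model, "B", "A")
  expect_same_bridges(rep$salt_bridges, fx$ground_truth$salt_bridges)
  expect_same_pairings(rep$beta_pairings, fx$ground_truth$pairings)
  ins <- Filter(function(b) b$inserted, rep$burials)
  expect_equal(vapply(ins, `[[`, integer(1), "res_seq"),
               fx$ground_truth$insertions$res_seq)
  expect_equal(nrow(rep$low_confidence_flags), 0L)  # plddt 90 everywhere

  # distant chains: all feature lists empty
  apart <- gen_complex_fixture("apart", seed = 21)
  rep0 <- interface_report(apart$model, "B", "A")
  expect_equal(length(rep0$burials), 0L)
  expect_equal(nrow(rep0$salt_bridges), 0L)
  expect_equal(length(rep0$beta_pairings), 0L)
  expect_error(interface_report(fx$model, "Z", "A"), "absent")
})

test_that("low-confidence interface residues are flagged below the pLDDT threshold", {
  fx <- gen_complex_fixture("salt_bridge", seed = 6, plddt = 55)
  rep <- interface_report(fx$model, "B", "A")
  expect_gt(nrow(rep$low_confidence_flags), 0L)
  expect_true(all(rep$low_confidence_flags$confidence < 70))
})

test_that("conservation overlay annotates receptor residues and reports serialize to JSON", {
  fx <- gen_complex_fixture("salt_bridge", seed = 7)
  # receptor chain A has residue 1 (Arg): track over positions 1..5
  tr <- column_conservation(gen_msa("RCDEF", n_rows = 10,
                                    per_column_rate = 0, seed = 1)$alignment)
  rep <- interface_report(fx$model, "B", "A", conservation = tr)
  expect_equal(rep$conservation$score[rep$conservation$res_seq == 1], 1)
  f <- tmp_file(".json")
  write_interface_json(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$client_chain, "B")
  expect_equal(back$salt_bridges[[1]]$kind, "side-chain")
})

test_that("Ramachandran classification honours residue-class geometry", {
  expect_equal(ramachandran_class(-63, -43, "general"), "favored")
  expect_equal(ramachandran_class(-139, 135, "general"), "favored")
  expect_equal(ramachandran_class(75, 5, "general"), "outlier")
  expect_true(ramachandran_class(75, 5, "glycine") %in% c("favored", "allowed"))
  # proline phi is restricted near -60
  expect_equal(ramachandran_class(-63, 150, "proline"), "favored")
  expect_equal(ramachandran_class(60, -120, "proline"), "outlier")
  # out-of-range angles are wrapped, not rejected
  expect_equal(ramachandran_class(-63 + 360, -43 - 360, "general"), "favored")
  # vectorized
  expect_equal(ramachandran_class(c(-63, -139), c(-43, 135)),
               c("favored", "favored"))
})

test_that("backbone dihedrals of an ideal strand land in the beta region", {
  fx <- gen_complex_fixture("beta_antiparallel", seed = 8, beta_length = 6,
                            jitter = 0)
  di <- backbone_dihedrals(fx$model, "A")
  mid <- !is.na(di$phi) & !is.na(di$psi)
  expect_gte(sum(mid), 4L)
  cls <- ramachandran_class(di$phi[mid], di$psi[mid])
  expect_true(all(cls %in% c("favored", "allowed")))
})
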