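test_that("separate-ion assembly shares ion blocks verbatim", {
  ils <- fixture_ils()
  idesc <- fixture_ion_descriptors()
  m <- assemble_separate(ils, idesc)
  expect_s3_class(m, "descriptor_matrix")
  expect_equal(attr(m, "representation"), "separate_ions")
  # anion block before cation block, alphabetical within block
  expect_equal(names(m)[-1],
               c(paste0(sort(c("AMW", "GMTI", "MDDD", "Psi_i_0", "SMTIV")),
                        "^A"),
                 paste0(sort(c("AMW", "GMTI", "MDDD", "Psi_i_0", "SMTIV")),
                        "^C")))
  # any two ILs sharing an anion have bitwise-identical ^A sub-rows
  acols <- grep("\\^A$", names(m), value = TRUE)
  for (an in unique(ils$anion_id)) {
    rows <- m[ils$anion_id == an, acols, drop = FALSE]
    for (cl in acols) expect_length(unique(rows[[cl]]), 1)
  }
})

test_that("imported ion-level table propagates identical anion values", {
  fx <- load_fixtures()
  t3_ils <- fx$ils[fx$ils$il_id %in%
                     c("[C4mpy][SCN]", "[C8mim][SCN]",
                       "[C4mpyrr][NTf2]", "[C4mpyrr][Br]"), ]
  m <- assemble_separate(t3_ils, fx$table3)
  scn <- m[t3_ils$anion_id == "SCN", ]
  expect_equal(scn[["L1i^A"]], c(1.38, 1.38))
  pyrr <- m[t3_ils$cation_id == "C4mpyrr", ]
  expect_equal(pyrr[["L1m^C"]], c(4.48, 4.48))
})

test_that("additive pair assembly weights ion values as specified", {
  reg <- fixture_registry()
  tab <- data.frame(ion_id = c("Br", "C4mim"), role = c("anion", "cation"),
                    GMTI = c(1, 6), stringsAsFactors = FALSE)
  ils <- ilqsar:::build_il_table(
    data.frame(il_id = "x", cation_id = "C4mim", anion_id = "Br",
               n_cation = 1L, n_anion = 1L, endpoint = NA_real_,
               stringsAsFactors = FALSE), reg)
  ms <- assemble_pair_additive(ils, tab)
  expect_equal(ms$GMTI, 7)
  mf <- assemble_pair_additive(ils, tab, weighting = "mole_fraction")
  expect_equal(mf$GMTI, 3.5)
})

test_that("pair AMW equals AMW of the disconnected union graph", {
  reg <- fixture_registry()
  ils <- fixture_ils()
  idesc <- fixture_ion_descriptors()
  m <- assemble_pair_additive(ils, idesc)
  for (r in c(1, 8, 17)) {
    u <- graph_union(list(ion_graph(reg, ils$cation_id[r]),
                          ion_graph(reg, ils$anion_id[r])))
    expect_equal(m$AMW[r], amw(u))
    # MDDD recombination reproduces the union-graph computation as well
    expect_equal(m$MDDD[r],
                 unname(suppressWarnings(
                   compute_all(u, "MDDD", on_disconnected = "combine"))))
  }
})

test_that("stoichiometric pair assembly is linear in the ion vectors", {
  reg <- fixture_registry()
  ils <- fixture_ils()[1:6, ]
  base <- fixture_ion_descriptors()
  d1 <- base[, c("ion_id", "role", "GMTI", "SMTIV")]
  d2 <- d1; d2$GMTI <- 2 * d2$GMTI; d2$SMTIV <- d2$SMTIV + 5
  dsum <- d1
  dsum$GMTI <- d1$GMTI + d2$GMTI; dsum$SMTIV <- d1$SMTIV + d2$SMTIV
  m1 <- assemble_pair_additive(ils, d1)
  m2 <- assemble_pair_additive(ils, d2)
  ms <- assemble_pair_additive(ils, dsum)
  expect_equal(dm_values(ms), dm_values(m1) + dm_values(m2))
})

test_that("pair matrices have about half the columns of separate ones", {
  ils <- fixture_ils()
  idesc <- fixture_ion_descriptors()
  n_sep <- ncol(assemble_separate(ils, idesc)) - 1L
  n_pair <- ncol(assemble_pair_additive(ils, idesc)) - 1L
  expect_equal(n_pair / n_sep, 0.5, tolerance = 0.1)
})

test_that("imported pair tables merge by il_id with provenance", {
  fx <- load_fixtures()
  t4_ils <- fx$ils[fx$ils$anion_id == "NTf2", ]
  idesc <- fixture_ion_descriptors()
  m <- assemble_pair_additive(t4_ils, idesc, imported = list(fx$table4))
  expect_true(all(c("L/Bw", "RTv", "L3u") %in% names(m)))
  expect_equal(m[["RTv"]][m$il_id == "[C8mim][NTf2]"], 7.20)
  expect_equal(unname(attr(m, "provenance")["RTv"]), "imported-3D")
  expect_equal(unname(attr(m, "provenance")["GMTI"]), "computed-2D")
  # key mismatch names the offending ILs
  expect_error(
    assemble_pair_additive(fixture_ils(), idesc,
                           imported = list(fx$table4)),
    "\\[C4mim\\]\\[Br\\]")
})

test_that("empty imported table is a warning no-op", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("il_id", tmp)
  expect_warning(t0 <- import_descriptor_table(tmp, level = "pair"),
                 "empty")
  ils <- fixture_ils()
  m <- assemble_pair_additive(ils, fixture_ion_descriptors(),
                              imported = list(t0))
  expect_equal(ncol(m) - 1L, 5L)
})

test_that("filter_variables drops constants and later correlated columns", {
  set.seed(11)
  df <- data.frame(il_id = sprintf("il%02d", 1:20),
                   a = rnorm(20), b = 5.0, check.names = FALSE)
  df$c <- df$a * 2          # |r| = 1 with a
  df$d <- rnorm(20)         # independent
  m <- ilqsar:::new_descriptor_matrix(df, "ionic_pair",
                                      c(a = "computed-2D", b = "computed-2D",
                                        c = "computed-2D", d = "computed-2D"))
  out <- filter_variables(m, corr_max = 0.95)
  expect_equal(out$report$dropped_constant, "b")
  expect_equal(out$report$dropped_correlated$dropped, "c")
  expect_equal(out$report$dropped_correlated$kept, "a")
  expect_equal(out$report$dropped_correlated$abs_r, 1.0)
  expect_setequal(setdiff(names(out$matrix), "il_id"), c("a", "d"))
  # idempotence
  again <- filter_variables(out$matrix, corr_max = 0.95)
  expect_equal(dm_values(again$matrix), dm_values(out$matrix))
  expect_equal(nrow(again$report$dropped_correlated), 0)
})

test_that("column_range reproduces the printed reference ranges", {
  fx <- load_fixtures()
  t4_ils <- fx$ils[fx$ils$anion_id == "NTf2", ]
  m <- assemble_pair_additive(t4_ils, fixture_ion_descriptors(),
                              imported = list(fx$table4))
  expect_equal(column_range(m, "L/Bw"), 1.17)
  expect_equal(column_range(m, "RTv"), 0.69)
  # constant column
  df <- data.frame(il_id = c("a", "b"), k = c(2, 2), check.names = FALSE)
  mc <- ilqsar:::new_descriptor_matrix(df, "ionic_pair", c(k = "computed-2D"))
  expect_equal(column_range(mc, "k"), 0)
  expect_error(column_range(mc, "nope"), "no column")
})
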