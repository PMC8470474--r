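classify_preset <- function(preset, ...) {
  g <- make_ig_domain(sandwich_spec(preset, ...))
  ann <- label_ig_strands(detect_strands(g$structure, "A"))
  classify_topology(ann)
}

test_that("every noise-free preset classifies as its own topology class", {
  for (preset in c("V_set", "C1_set", "C2_set", "I_set", "FN3", "cadherin")) {
    tc <- classify_preset(preset)
    expect_equal(tc$label, preset, info = preset)
    expect_gt(length(tc$rule_trace), 0)
  }
})

test_that("rule order makes C'' decisive even with a short C'", {
  # an I-set-like domain plus a C'' strand must classify V-set (rule 1 first)
  g <- make_ig_domain(sandwich_spec("V_set"))
  tc <- classify_preset("V_set")
  expect_match(tc$rule_trace[1], "rule 1")
  expect_equal(tc$label, "V_set")
})

test_that("the CCW(L) signature separates the C2-set from FN3", {
  c2 <- classify_preset("C2_set")   # decorated by default
  expect_equal(c2$label, "C2_set")
  expect_gte(c2$signature$n_strict, 3)
  fn <- classify_preset("FN3")      # poly-alanine by default
  expect_equal(fn$label, "FN3")
  expect_equal(fn$signature$n_strict, 0)
  # forcing the decoration onto the same strand table flips the call
  forced <- classify_preset("FN3", sequence_mode = "ccwl_decorated")
  expect_equal(forced$label, "C2_set")
})

test_that("signature positions land on their named strands", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  ann <- label_ig_strands(detect_strands(g$structure, "A"))
  sig <- detect_ccwl(ann)
  expect_true(sig$complete)
  for (nm in names(sig$positions)) {
    strand <- igproto:::annotation_strand(ann, sub("._in_", "", nm))
    # position lies on the named strand (allowing the one-residue flank)
    pos <- as.integer(sig$positions[[nm]])
    expect_true(pos >= min(strand$resno) - 1 && pos <= max(strand$resno) + 1)
  }
  gp <- make_ig_domain(sandwich_spec("V_set", sequence_mode = "poly_ala"))
  sigp <- detect_ccwl(label_ig_strands(detect_strands(gp$structure, "A")))
  expect_false(sigp$complete)
  expect_equal(sigp$n_strict, 0)
  expect_true(all(is.na(unlist(sigp$positions))))
})

test_that("an incomplete signature does not reclassify a V-set domain", {
  tc <- classify_preset("V_set", sequence_mode = "poly_ala")
  expect_equal(tc$label, "V_set")   # CD2-like: missing pattern tolerated
})

test_that("the interdigitated double Ig fold is detected with all evidence", {
  g <- make_ig_domain(sandwich_spec("double_Ig"))
  scan <- detect_double_ig(g$structure, "A")
  expect_true(scan$found)
  m <- scan$model
  expect_length(m$protodomains, 4)
  expect_equal(m$protodomains[[1]]$strand_labels, c("A'", "B", "C", "C'"))
  expect_equal(m$protodomains[[2]]$strand_labels, c("D", "E", "F", "G"))
  # (a) short parallel linkers
  for (lk in m$parallel_pairs) {
    expect_lte(lk$length, igproto_config()$short_linker_max)
    expect_lt(lk$b_e_angle, 90)
  }
  # (b) long inverter between the halves
  expect_gt(diff(m$inverter_linker) + 1, igproto_config()$inverter_min)
  # (c) fused sheets through C'|C' and D|D ladders
  expect_gte(m$fused_sheet_evidence$c_prime, 2)
  expect_gte(m$fused_sheet_evidence$d, 2)
  # composite domains: (p1,p4) regular, (p2,p3) inverse (DE-FG precedes AB-CC')
  expect_false(m$composite_domains$regular$inverse)
  expect_true(m$composite_domains$inverse$inverse)
  # central C2 is exact by construction
  expect_equal(m$axes$central$angle, 180, tolerance = 1e-9)
  expect_lt(m$central_superposition$rmsd, 1e-9)
  expect_equal(m$axes$local_p1_p4$angle, 180, tolerance = 5)
})

test_that("a single Ig domain is not reported as a double Ig fold", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  scan <- detect_double_ig(g$structure, "A")
  expect_false(scan$found)
  expect_gt(length(scan$diagnostic), 0)
})

test_that("the inverse-Ig flag is purely sequential", {
  g <- make_ig_domain(sandwich_spec("double_Ig"))
  m <- detect_double_ig(g$structure, "A")$model
  inv <- m$composite_domains$inverse$members
  p <- m$protodomains
  # the DE-FG member of the inverse composite precedes its AB-CC' member
  defg <- inv[vapply(inv, function(i) "E" %in% p[[i]]$strand_labels, logical(1))]
  abcc <- setdiff(inv, defg)
  expect_lt(min(p[[defg]]$strands[[1]]$idx), min(p[[abcc]]$strands[[1]]$idx))
})

test_that("topology maps render both sheets in lateral order", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  ann <- label_ig_strands(detect_strands(g$structure, "A"))
  tm <- topology_map(ann)
  expect_length(tm$sheets, 2)
  rows <- lapply(tm$sheets, function(sh) vapply(sh, `[[`, "", "label"))
  expect_setequal(unlist(rows), c("A", "B", "E", "D", "A'", "G", "F", "C", "C'", "C''"))
  abed <- rows[[which(vapply(rows, function(r) "B" %in% r, logical(1)))]]
  expect_true(identical(abed, c("A", "B", "E", "D")) ||
              identical(abed, rev(c("A", "B", "E", "D"))))
  txt <- format(tm)
  expect_true(any(grepl("CDR1", txt)))
  expect_type(txt, "character")
  # colors follow the protodomain scheme
  colr <- unlist(lapply(unlist(tm$sheets, recursive = FALSE), function(r)
    stats::setNames(list(r$color), r$label)), recursive = FALSE)
  expect_equal(colr[["B"]], "green"); expect_equal(colr[["E"]], "green")
  expect_equal(colr[["C''"]], "red"); expect_equal(colr[["A"]], "blue")
})

test_that("the double-Ig map shows the two fused long sheets", {
  g <- make_ig_domain(sandwich_spec("double_Ig"))
  m <- detect_double_ig(g$structure, "A")$model
  tm <- topology_map(m)
  expect_length(tm$sheets, 2)
  rows <- lapply(tm$sheets, function(sh) vapply(sh, `[[`, "", "label"))
  bed <- rows[[which(vapply(rows, function(r) "B1" %in% r, logical(1)))]]
  # (BED)1(DEB)2: the two D strands are adjacent at the fusion
  expect_setequal(bed, c("B1", "E2", "D2", "D4", "E4", "B3"))
  d_pos <- which(grepl("^D", bed))
  expect_equal(abs(diff(d_pos)), 1)
})

test_that("the VNAR flag is an opt-in heuristic on I-set domains", {
  g <- make_ig_domain(sandwich_spec("I_set", sequence_mode = "poly_ala"))
  ann <- label_ig_strands(detect_strands(g$structure, "A"))
  # hydrophobic (poly-Ala) GFCC' face: stays I_set even with the heuristic on
  tc <- classify_topology(ann, vnar_heuristic = TRUE)
  expect_equal(tc$label, "I_set")
  expect_match(tc$notes, "hydrophilic", all = FALSE)
  # default call never reports VNAR_like
  expect_equal(classify_topology(ann)$label, "I_set")
})
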