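ann_of <- function(preset, ...) {
  g <- make_ig_domain(sandwich_spec(preset, ...))
  list(ann = label_ig_strands(detect_strands(g$structure, "A")),
       st = g$structure, truth = g$truth)
}

test_that("decomposition yields the AB-CC' and DE-FG units with the class linker", {
  v <- ann_of("V_set")
  pd <- decompose(v$ann)
  expect_equal(pd[[1]]$strand_labels, c("A", "A'", "B", "C", "C'"))
  expect_equal(pd[[2]]$strand_labels, c("D", "E", "F", "G"))
  expect_equal(pd[[1]]$linker$name, "CDR2+C''+C''D")
  fn3 <- ann_of("FN3")
  pf <- decompose(fn3$ann)
  expect_equal(pf[[1]]$strand_labels, c("A", "B", "C", "C'"))
  expect_equal(pf[[2]]$strand_labels, c("E", "F", "G"))   # no D strand
  expect_equal(pf[[1]]$linker$name, "C'-E")
  expect_equal(decompose(ann_of("I_set")$ann)[[1]]$linker$name, "C'-D")
  expect_equal(decompose(ann_of("cadherin")$ann)[[1]]$linker$name, "C-D")
})

test_that("decomposition requires the core and an is_ig annotation", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  at <- g$structure$atoms
  half <- new_structure(at[at$resno <= 40, , drop = FALSE])
  ann <- label_ig_strands(detect_strands(half, "A"))
  expect_error(decompose(ann), "cannot decompose")
})

test_that("center-trim pairing keeps the window toward the N side on ties", {
  tp <- igproto:::trim_pair(1:6, 1:6)
  expect_equal(nrow(tp), 6)
  expect_equal(tp[, 1], tp[, 2])
  tp <- igproto:::trim_pair(1:7, 1:4)           # 7-mer trimmed to central 4
  expect_equal(tp[, 1], 2:5)
  expect_equal(tp[, 2], 1:4)
  tp <- igproto:::trim_pair(1:4, 1:7)
  expect_equal(tp[, 2], 2:5)
})

test_that("correspondence maps only symmetry-equivalent strands", {
  v <- ann_of("V_set")
  pd <- decompose(v$ann)
  corr <- build_correspondence(pd[[1]], pd[[2]])
  expect_setequal(unique(paste(corr$pairs$strand_i, corr$pairs$strand_j)),
                  c("A D", "B E", "C F", "C' G"))
  expect_false("A'" %in% corr$pairs$strand_i)   # A' stays unmatched
  sub <- build_correspondence(pd[[1]], pd[[2]], strands = c("B", "C", "C'"))
  expect_setequal(unique(sub$pairs$strand_i), c("B", "C", "C'"))
  # one-to-one pairing
  expect_false(anyDuplicated(corr$pairs$key_i) > 0)
  expect_false(anyDuplicated(corr$pairs$key_j) > 0)
})

test_that("cadherin-type domains pair three strand pairs (A on the G-side sheet)", {
  cad <- ann_of("cadherin")
  pd <- decompose(cad$ann)
  corr <- build_correspondence(pd[[1]], pd[[2]])
  expect_setequal(unique(paste(corr$pairs$strand_i, corr$pairs$strand_j)),
                  c("B E", "C F"))
  sp <- superpose(corr, cad$st)
  expect_lt(sp$rmsd, 1e-9)
})

test_that("noise-free domains superpose exactly with a clean C2 axis", {
  for (preset in c("V_set", "C1_set", "I_set", "FN3")) {
    x <- ann_of(preset)
    ps <- protodomain_symmetry(x$ann, x$st)
    expect_lt(ps$superposition$rmsd, 1e-9)
    expect_equal(ps$axis$angle, 180, tolerance = 1e-9)
    expect_lt(abs(ps$axis$screw), 1e-9)
    expect_lt(igproto:::line_angle(ps$axis$direction,
                                   x$truth$axes$tertiary$direction), 1e-6)
    expect_equal(ps$axis$order_label, "C2")
  }
})

test_that("refinement drops badly fitting pairs and cannot worsen the RMSD", {
  x <- ann_of("V_set", noise_sigma = 0.6, seed = 3)
  pd <- decompose(x$ann)
  corr <- build_correspondence(pd[[1]], pd[[2]])
  plain <- superpose(corr, x$st)
  ref <- superpose(corr, x$st, refine = TRUE,
                   config = igproto_config(refine_pair_cutoff = 1.0))
  expect_lte(ref$n_pairs, plain$n_pairs)
  expect_lte(ref$rmsd, plain$rmsd + 1e-12)
  expect_true(ref$refined)
})

test_that("paired sequence identity is reported on paired positions only", {
  x <- ann_of("V_set")     # decorated: C/W on p1 vs L/C on p2 at paired centers
  pd <- decompose(x$ann)
  corr <- build_correspondence(pd[[1]], pd[[2]])
  id <- paired_identity(corr, x$st)
  expect_gte(id, 0); expect_lt(id, 1)
  self <- build_correspondence(pd[[1]], pd[[1]],
                               pair_map = stats::setNames(pd[[1]]$strand_labels,
                                                          pd[[1]]$strand_labels))
  expect_equal(paired_identity(self, x$st), 1)
})
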