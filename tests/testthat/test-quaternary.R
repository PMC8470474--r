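test_that("parallel and inverted ideal dimers are classified with exact D2 geometry", {
  for (preset in c("parallel_dimer", "inverted_dimer")) {
    g <- make_dimer(sandwich_spec(preset))
    st <- g$structure
    dA <- ig_domain(st, "A"); dB <- ig_domain(st, "B")
    geo <- quaternary_axis_and_orientation(st, dA, dB)
    expect_equal(geo$orientation, g$truth$orientation, info = preset)
    expect_equal(geo$quaternary_axis$angle, 180, tolerance = 1e-9)
    expect_lt(geo$quaternary_rmsd, 1e-9)
    expect_lt(igproto:::line_angle(geo$quaternary_axis$direction,
                                   g$truth$axes$quaternary$direction), 1e-6)
    # quasi-D2: collinear tertiary axes, orthogonal quaternary axis, no offset
    expect_lt(geo$d2_report$tertiary_tertiary_angle, 1e-6)
    expect_equal(unname(geo$d2_report$tertiary_quaternary_angle), c(90, 90),
                 tolerance = 1e-6)
    expect_lt(geo$d2_report$center_offset, 1e-6)
  }
})

test_that("G-strand angle bands define parallel vs inverted", {
  gp <- make_dimer(sandwich_spec("parallel_dimer"))
  geo <- quaternary_axis_and_orientation(gp$structure,
                                         ig_domain(gp$structure, "A"),
                                         ig_domain(gp$structure, "B"))
  expect_lt(geo$g_angle, 60)
  gi <- make_dimer(sandwich_spec("inverted_dimer"))
  geo2 <- quaternary_axis_and_orientation(gi$structure,
                                          ig_domain(gi$structure, "A"),
                                          ig_domain(gi$structure, "B"))
  expect_gt(geo2$g_angle, 120)
})

test_that("orientation is invariant to partner order and rigid motion", {
  g <- make_dimer(sandwich_spec("inverted_dimer", noise_sigma = 0.2, seed = 8))
  st <- g$structure
  dA <- ig_domain(st, "A"); dB <- ig_domain(st, "B")
  o1 <- quaternary_axis_and_orientation(st, dA, dB)$orientation
  o2 <- quaternary_axis_and_orientation(st, dB, dA)$orientation
  expect_equal(o1, o2)
  set.seed(21)
  st2 <- move_structure(st, random_rotation(), c(30, -10, 5))
  o3 <- quaternary_axis_and_orientation(st2, ig_domain(st2, "A"),
                                        ig_domain(st2, "B"))$orientation
  expect_equal(o1, o3)
})

test_that("the canonical dimer interface is attributed to the GFCC' sheet", {
  g <- make_dimer(sandwich_spec("parallel_dimer"))
  st <- g$structure
  iface <- find_interface(st, ig_domain(st, "A"), ig_domain(st, "B"))
  expect_false(iface$empty)
  expect_equal(iface$attribution$A$category, "GFCC'")
  expect_equal(iface$attribution$B$category, "GFCC'")
  expect_equal(sum(iface$attribution$A$strand_fractions), 1, tolerance = 1e-9)
})

test_that("interface attribution is stable to a +/- 0.3 A cutoff change", {
  g <- make_dimer(sandwich_spec("parallel_dimer", noise_sigma = 0.2, seed = 4))
  st <- g$structure
  dA <- ig_domain(st, "A"); dB <- ig_domain(st, "B")
  cats <- vapply(c(4.2, 4.5, 4.8), function(ct)
    find_interface(st, dA, dB, cutoff = ct)$attribution$A$category, character(1))
  expect_equal(unique(cats), "GFCC'")
})

test_that("far-apart domains give a typed empty interface", {
  g1 <- make_ig_domain(sandwich_spec("V_set"))
  at2 <- g1$structure$atoms
  at2$chain <- "B"; at2$x <- at2$x + 500
  st <- new_structure(rbind(g1$structure$atoms, at2))
  iface <- find_interface(st, ig_domain(st, "A"), ig_domain(st, "B"))
  expect_s3_class(iface, "DimerInterface")
  expect_true(iface$empty)
  expect_equal(iface$n_contacts, 0)
})

test_that("protodomain swaps are detected and canonical dimers are not", {
  gs <- make_dimer(sandwich_spec("swapped_dimer"))
  rep_s <- detect_protodomain_swap(gs$structure, "A", "B")
  expect_true(rep_s$swapped)
  expect_equal(rep_s$status, "swapped")
  expect_false(is.null(rep_s$linkers$A))
  # the swap linkers are extended relative to a protodomain linker
  expect_gt(diff(rep_s$linkers$A) + 1, igproto_config()$short_linker_max)
  gc <- make_dimer(sandwich_spec("parallel_dimer"))
  rep_c <- detect_protodomain_swap(gc$structure, "A", "B")
  expect_false(rep_c$swapped)
  expect_equal(rep_c$status, "canonical")
})

test_that("swap closure evidence separates cross from sequential pairings", {
  g <- make_dimer(sandwich_spec("swapped_dimer", noise_sigma = 0.3, seed = 5))
  rep <- detect_protodomain_swap(g$structure, "A", "B")
  expect_true(rep$swapped)
  expect_gt(rep$evidence["cross"], 0)
  expect_equal(unname(rep$evidence["sequential"]), 0)
})
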