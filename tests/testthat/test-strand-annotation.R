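test_that("a noise-free V-type sandwich yields 10 strands on two sheets with one parallel ladder", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  det <- detect_strands(g$structure, "A")
  expect_length(det$strands, 10)
  expect_length(unique(det$sheet_ids), 2)
  par <- det$adjacency[det$adjacency$orientation == "parallel", ]
  expect_equal(nrow(par), 1)       # the designed A'/G pair is the only one
  ann <- label_ig_strands(det)
  lab_of <- function(k) ann$strands[[k]]$label
  expect_setequal(c(lab_of(par$s1), lab_of(par$s2)), c("A'", "G"))
})

test_that("strand boundaries and labels match the generator ground truth under noise", {
  for (sd in c(2, 7, 13)) {
    g <- make_ig_domain(sandwich_spec("V_set", noise_sigma = 0.3, seed = sd))
    ann <- label_ig_strands(detect_strands(g$structure, "A"))
    expect_true(ann$is_ig)
    tt <- g$truth$residues
    for (s in ann$strands) {
      if (is.na(s$label)) next
      true_res <- tt$resno[!is.na(tt$label) & tt$label == s$label]
      # detected strand overlaps its true extent by at least 2 residues
      expect_gte(length(intersect(s$resno, true_res)), 2)
    }
  }
})

test_that("canonical labels per topology preset match the design", {
  ann1 <- label_ig_strands(detect_strands(make_ig_domain(sandwich_spec("C1_set"))$structure, "A"))
  expect_setequal(setdiff(annotation_labels(ann1), ""),
                  c("A", "B", "C", "D", "E", "F", "G"))
  expect_false(ann1$a_split)
  expect_setequal(ann1$sheet_A, c("A", "B", "E", "D"))
  expect_setequal(ann1$sheet_B, c("G", "F", "C"))
  annv <- label_ig_strands(detect_strands(make_ig_domain(sandwich_spec("V_set"))$structure, "A"))
  expect_true(annv$a_split)
  expect_true("A" %in% annv$sheet_A && "A'" %in% annv$sheet_B)
  expect_setequal(annv$sheet_B, c("A'", "G", "F", "C", "C'", "C''"))
  # CDR1 spans the B-C connection, CDR3 the F-G connection
  b <- igproto:::annotation_strand(annv, "B"); c_ <- igproto:::annotation_strand(annv, "C")
  expect_true(annv$loops$CDR1[1] > max(b$resno) && annv$loops$CDR1[2] < min(c_$resno))
  f <- igproto:::annotation_strand(annv, "F"); gg <- igproto:::annotation_strand(annv, "G")
  expect_true(annv$loops$CDR3[1] > max(f$resno) && annv$loops$CDR3[2] < min(gg$resno))
})

test_that("backbone H-bond mode agrees with the Ca-only mode on clean input", {
  g <- make_ig_domain(sandwich_spec("I_set", atom_mode = "full"))
  ann_ca <- label_ig_strands(detect_strands(g$structure, "A", mode = "ca_only"))
  ann_bb <- label_ig_strands(detect_strands(g$structure, "A", mode = "backbone"))
  expect_true(ann_bb$is_ig)
  lab <- function(a) sort(setdiff(annotation_labels(a), ""))
  expect_equal(lab(ann_bb), lab(ann_ca))
})

test_that("annotation is deterministic", {
  g <- make_ig_domain(sandwich_spec("I_set", noise_sigma = 0.3, seed = 9))
  a1 <- label_ig_strands(detect_strands(g$structure, "A"))
  a2 <- label_ig_strands(detect_strands(g$structure, "A"))
  expect_identical(annotation_labels(a1), annotation_labels(a2))
  expect_identical(lapply(a1$strands, `[[`, "resno"),
                   lapply(a2$strands, `[[`, "resno"))
})

test_that("structures without the core straddle get a typed not-Ig verdict", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  at <- g$structure$atoms
  half <- new_structure(at[at$resno <= 40, , drop = FALSE])
  ann <- label_ig_strands(detect_strands(half, "A"))
  expect_s3_class(ann, "IgAnnotation")
  expect_false(ann$is_ig)
  expect_match(ann$reason, "straddle|sheets|strands")
})

test_that("manual override wins over detection and is validated", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  det <- detect_strands(g$structure, "A")
  tt <- g$truth$residues
  rng <- function(l) range(tt$resno[!is.na(tt$label) & tt$label == l])
  ov <- lapply(c("A", "A'", "B", "C", "C'", "C''", "D", "E", "F", "G"), rng)
  names(ov) <- c("A", "A'", "B", "C", "C'", "C''", "D", "E", "F", "G")
  ann <- label_ig_strands(det, override = ov)
  expect_true(ann$is_ig)
  expect_true(ann$a_split)
  expect_equal(igproto:::annotation_strand(ann, "B")$resno,
               seq(rng("B")[1], rng("B")[2]))
  bad <- ov; bad$C <- bad$B                       # overlapping intervals
  expect_error(label_ig_strands(det, override = bad), "override validation")
  expect_error(label_ig_strands(det, override = list(Z = c(1, 5))), "unknown label")
})

test_that("chains below the size floor are rejected with a clear error", {
  g <- make_ig_domain(sandwich_spec("V_set"))
  at <- g$structure$atoms
  tiny <- new_structure(at[at$resno <= 15, , drop = FALSE])
  expect_error(detect_strands(tiny, "A"), "fewer than 20")
})
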