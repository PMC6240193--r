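# Small deterministic annotation table: peptides with known cores/contexts.
toy_annotations <- function() {
  lig <- data.frame(
    peptide = c("APKFAYSWAADKILK",   # 15mer, offset 3 -> PFRs 3/3
                "FAYSWAADKLL",       # 11mer, offset 0 -> PFRs 0/2
                "KPAFAYSWAADKRRR"),  # 15mer, offset 4 -> PFRs 4/2
    target = 1, data_type = "EL",
    context_up = c("LMN", "QRS", "TVW"),
    context_down = c("DEG", "HIK", "MNP"),
    source_protein_id = NA_character_, stringsAsFactors = FALSE)
  annotate_pfr(lig, c(3L, 0L, 4L))
}

test_that("PFR arithmetic follows the core offset", {
  ann <- toy_annotations()
  expect_equal(ann$n_pfr, c(3L, 0L, 4L))
  expect_equal(ann$c_pfr, c(3L, 2L, 2L))
  expect_true(all(ann$n_pfr + 9 + ann$c_pfr == nchar(ann$peptide)))
})

test_that("context is looked up from the source protein when absent", {
  prot <- c(SP1 = paste0("MKL", "APKFAYSWAADKILK", "QPW", "AAAA"))
  lig <- data.frame(peptide = "APKFAYSWAADKILK", target = 1,
                    data_type = "EL", context_up = NA_character_,
                    context_down = NA_character_,
                    source_protein_id = "SP1", stringsAsFactors = FALSE)
  ann <- annotate_pfr(lig, 3L, prot)
  expect_equal(ann$context_up, "MKL")
  expect_equal(ann$context_down, "QPW")
  # N-terminal ligand: upstream context padded with X
  prot2 <- c(SP2 = paste0("APKFAYSWAADKILK", "QPW"))
  ann2 <- annotate_pfr(within(lig, source_protein_id <- "SP2"), 3L, prot2)
  expect_equal(ann2$context_up, "XXX")
  # ligand absent from its protein is excluded with a message
  expect_message(
    ann3 <- annotate_pfr(rbind(lig, within(lig, peptide <- "WWWWWWWWWWWWWWW")),
                         c(3L, 3L), prot),
    "excluded 1")
  expect_equal(nrow(ann3), 1)
})

test_that("PFR arithmetic identity holds across generated ligands", {
  w <- tiny_world(3, n_ligands = 200)
  em <- emit_ligands(w)
  ann <- annotate_pfr(em$ligands[, 1:6], em$ligands$true_offset, em$proteins)
  expect_true(all(ann$n_pfr + 9 + ann$c_pfr == nchar(ann$peptide)))
})

test_that("terminal matrix enforces the PFR >= 3 filter", {
  ann <- toy_annotations()
  bg <- setNames(rep(0.05, 20), aa_alphabet())
  up <- terminal_matrix(ann, "upstream", background = bg)
  expect_equal(up$n_ligands, 2L)  # the 11mer with N-PFR 0 is dropped
  down <- terminal_matrix(ann, "downstream", background = bg)
  expect_equal(down$n_ligands, 1L)  # only the first ligand has C-PFR >= 3
  short <- ann[ann$n_pfr < 3, , drop = FALSE]
  expect_error(terminal_matrix(short, "upstream", background = bg),
               "no ligand passes")
})

test_that("a forced residue shows frequency one and counts conserve ligands", {
  w <- tiny_world(5, n_ligands = 150, cleavage_prob = 1)
  em <- emit_ligands(w)
  ann <- annotate_pfr(em$ligands[, 1:6], em$ligands$true_offset, em$proteins)
  bg <- setNames(rep(0.05, 20), aa_alphabet())
  up <- terminal_matrix(ann, "upstream", background = bg)
  # cleavage_prob 1: every ligand with N-PFR >= 3 has P at peptide position
  # 2, which is row 5 of the upstream matrix (3 context + position 2)
  expect_equal(up$frequencies[5, "P"], 1)
  expect_true(all(rowSums(up$counts) == up$n_ligands))
  expect_equal(rowSums(up$frequencies), rep(1, 6), ignore_attr = TRUE)
  down <- terminal_matrix(ann, "downstream", background = bg)
  expect_equal(down$frequencies[2, "P"], 1)  # second-from-C = row 2
})

test_that("KL logo heights follow the closed forms and a formula oracle", {
  q <- setNames(rep(0.05, 20), aa_alphabet())
  f_eq <- matrix(0.05, 2, 20, dimnames = list(NULL, aa_alphabet()))
  lg <- kl_logo_matrix(f_eq, q)
  expect_equal(lg$heights, f_eq * 0, ignore_attr = TRUE)
  expect_equal(lg$information, c(0, 0), ignore_attr = TRUE)
  f_conc <- matrix(0, 1, 20, dimnames = list(NULL, aa_alphabet()))
  f_conc[1, "P"] <- 1
  expect_equal(kl_logo_matrix(f_conc, q)$information, log2(20),
               ignore_attr = TRUE)
  set.seed(21)
  f <- matrix(rgamma(40, 1), 2, 20)
  f <- f / rowSums(f)
  qq <- rgamma(20, 2); qq <- qq / sum(qq)
  lg2 <- kl_logo_matrix(f, qq)
  for (i in 1:2) for (j in 1:20)
    expect_equal(lg2$heights[i, j], f[i, j] * log2(f[i, j] / qq[j]))
  expect_error(kl_logo_matrix(f, c(0, qq[-1])), "zero")
  expect_error(kl_logo_matrix(f * 2, qq), "sum to 1")
})

test_that("PFR-grouped logos have 3 + min(PFR, 6) positions", {
  w <- tiny_world(9, n_ligands = 300)
  em <- emit_ligands(w)
  ann <- annotate_pfr(em$ligands[, 1:6], em$ligands$true_offset, em$proteins)
  bg <- setNames(rep(0.05, 20), aa_alphabet())
  logos <- suppressMessages(pfr_grouped_logos(ann, "upstream",
                                              background = bg))
  expect_equal(nrow(logos$pfr_1$heights), 4)
  if (!is.null(logos$pfr_6)) expect_equal(nrow(logos$pfr_6$heights), 9)
  expect_equal(nrow(logos$pfr_3$heights), 6)
})

test_that("matrix PCC is 1 on itself, -1 on negation and symmetric", {
  w <- tiny_world(31, n_ligands = 300)
  em <- emit_ligands(w)
  ann <- annotate_pfr(em$ligands[, 1:6], em$ligands$true_offset, em$proteins)
  a <- terminal_matrix(ann, "upstream", em$proteins)
  expect_equal(matrix_pcc(a, a), 1.0)
  b <- a
  b$log_odds <- -a$log_odds
  expect_equal(matrix_pcc(a, b), -1.0)
  half <- annotate_pfr(em$ligands[1:150, 1:6],
                       em$ligands$true_offset[1:150], em$proteins)
  m2 <- terminal_matrix(half, "upstream", em$proteins)
  expect_equal(matrix_pcc(a, m2), matrix_pcc(m2, a))
  cst <- a
  cst$log_odds[] <- 0.3
  expect_error(matrix_pcc(a, cst), "constant")
  dn <- terminal_matrix(ann, "downstream", em$proteins)
  expect_error(matrix_pcc(a, dn), "different sides")
})

test_that("permutation-test p-values hit their boundary closed forms", {
  set.seed(22)
  wa <- tiny_world(41, n_ligands = 120, cleavage_prob = 0.8)
  wb <- tiny_world(42, n_ligands = 120, cleavage_prob = 0.8)
  ea <- emit_ligands(wa); eb <- emit_ligands(wb)
  aa <- annotate_pfr(ea$ligands[, 1:6], ea$ligands$true_offset, ea$proteins)
  ab <- annotate_pfr(eb$ligands[, 1:6], eb$ligands$true_offset, eb$proteins)
  bg <- setNames(rep(0.05, 20), aa_alphabet())
  set.seed(1)
  pt <- pcc_permutation_test(aa, ab, "upstream", n_perm = 99,
                             background = bg, null = "entries")
  # shared planted signal vs the no-correlation null: observed beats every
  # permutation
  expect_equal(pt$p_value, 1 / (1 + 99))
  expect_true(all(pt$null < pt$observed))
  expect_error(pcc_permutation_test(aa, ab, "upstream", n_perm = 0,
                                    background = bg), "n_perm")
})

test_that("permutation test is calibrated on exchangeable sets", {
  set.seed(23)
  w <- tiny_world(51, n_ligands = 240, cleavage_prob = 0.4)
  em <- emit_ligands(w)
  ann <- annotate_pfr(em$ligands[, 1:6], em$ligands$true_offset, em$proteins)
  bg <- setNames(rep(0.05, 20), aa_alphabet())
  reject <- logical(200)
  for (r in 1:200) {
    sel <- sample(nrow(ann), nrow(ann) / 2)
    p <- pcc_permutation_test(ann[sel, ], ann[-sel, ], "upstream",
                              n_perm = 19, background = bg)$p_value
    reject[r] <- p <= 0.05
  }
  # alpha = 0.05 with n_perm = 19 means p = 1/20; binomial 4-sigma band
  expect_lt(abs(mean(reject) - 0.05), 4 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("removing the cysteine column barely changes replicate PCC", {
  wa <- tiny_world(61, n_ligands = 400)
  wb <- tiny_world(62, n_ligands = 400)
  ea <- emit_ligands(wa); eb <- emit_ligands(wb)
  aa <- annotate_pfr(ea$ligands[, 1:6], ea$ligands$true_offset, ea$proteins)
  ab <- annotate_pfr(eb$ligands[, 1:6], eb$ligands$true_offset, eb$proteins)
  bg <- setNames(rep(0.05, 20), aa_alphabet())
  a <- terminal_matrix(aa, "upstream", background = bg)
  b <- terminal_matrix(ab, "upstream", background = bg)
  full <- matrix_pcc(a, b)
  noc <- matrix_pcc(a, b, drop_residues = "C")
  expect_lt(abs(full - noc), 0.1)
})
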