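test_that("PDB parsing handles single and multi-model input", {
  lines1 <- sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                    1:5, 1:5, seq(0, 12, 3), 0, 0)
  s <- parse_pdb(text = paste(c(lines1, "END"), collapse = "\n"))
  expect_s3_class(s, "chan_structure")
  expect_equal(n_atoms(s), 5)
  expect_equal(unique(s$atoms$chain), "A")
  expect_equal(s$atoms$x, seq(0, 12, 3))

  block <- function(m) c(sprintf("MODEL     %4d", m), lines1, "ENDMDL")
  txt <- paste(c(block(1), block(2), "END"), collapse = "\n")
  merged <- parse_pdb(text = txt, model_policy = "merge_all")
  expect_equal(n_atoms(merged), 10)
  expect_setequal(unique(merged$atoms$copy), c(0L, 1L))
  first <- parse_pdb(text = txt, model_policy = "first_only")
  expect_equal(n_atoms(first), 5)
  expect_equal(unique(first$atoms$copy), 0L)
})

test_that("unparseable input raises a structured parse error", {
  expect_error(parse_pdb(text = "HEADER    NOTHING\nEND"),
               class = "chanatomy_parse_error")
})

test_that("sanitize removes hydrogens, waters and distant HETATM groups", {
  mk <- function(rec, serial, name, resn, resno, x, het = FALSE, elem = NULL) {
    elem <- elem %||% substr(name, 1, 1)
    sprintf("%-6s%5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            if (het) "HETATM" else "ATOM", serial, name, resn, resno, x, 0, 0, elem)
  }
  prot <- sapply(1:6, function(i) mk("A", i, "CA", "ALA", i, (i - 1) * 3))
  hyd <- mk("A", 7, "H", "ALA", 1, 0.5)
  wat <- mk("A", 8, "O", "HOH", 50, 30, het = TRUE)
  near <- mk("A", 9, "C1", "LIG", 60, 15 + 1.5, het = TRUE) # 1.5 A from last CA
  far <- mk("A", 10, "C1", "LG2", 61, 15 + 3.5, het = TRUE)
  s <- parse_pdb(text = paste(c(prot, hyd, wat, near, far, "END"), collapse = "\n"))
  clean <- sanitize(s)
  expect_equal(n_atoms(clean), 7) # 6 CA + covalent LIG
  expect_true("LIG" %in% clean$atoms$resname)
  expect_false("LG2" %in% clean$atoms$resname)
  expect_false(any(clean$atoms$element == "H"))
  expect_false("HOH" %in% clean$atoms$resname)
  # idempotence
  expect_identical(sanitize(clean)$atoms, clean$atoms)
  # drop_all removes even the covalent group
  expect_equal(n_atoms(sanitize(s, "drop_all")), 6)
})

test_that("sanitize rejects degenerate results", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0))
  lines <- sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   1:2, 1:2, xyz[, 1], xyz[, 2], xyz[, 3])
  s <- parse_pdb(text = paste(c(lines, "END"), collapse = "\n"))
  expect_error(sanitize(s), class = "chanatomy_degenerate_error")
})

test_that("radius assignment follows the Bondi table with a default fallback", {
  s <- make_test_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(9, 0, 0)),
                           element = c("C", "O", "N", "S"))
  expect_equal(s$atoms$radius, c(1.70, 1.52, 1.55, 1.80))
  s2 <- parse_pdb(text = paste(c(
    sprintf("ATOM  %5d  XX  UNK A%4d    %8.3f%8.3f%8.3f  1.00  0.00           X",
            1:4, 1:4, c(0, 3, 6, 9), 0, 0), "END"), collapse = "\n"))
  expect_warning(s2 <- assign_radii(s2), "default radius")
  expect_equal(unique(s2$atoms$radius), 1.70)
  expect_error(radius_table(values = c(C = 3.5)), class = "chanatomy_value_error")
})

test_that("parse -> write -> parse round trip preserves the structure", {
  syn <- quick_tunnel(seed = 31, length = 18)
  f <- tempfile(fileext = ".pdb")
  write_pdb(syn$structure, f)
  back <- assign_radii(parse_pdb(file = f))
  expect_equal(n_atoms(back), n_atoms(syn$structure))
  expect_equal(back$atoms$x, round(syn$structure$atoms$x, 3))
  expect_equal(back$atoms$resname, syn$structure$atoms$resname)
  expect_equal(back$atoms$resno, syn$structure$atoms$resno)
})

test_that("manifest loading validates schema, EC classes and thresholds", {
  txt <- paste(
    "structure_id,ec,structure_path,sites_path,resolution",
    "A1,1.1.1.1,a.pdb,a.csv,1.8",
    "A2,3.4.21,b.pdb,b.csv,2.4",
    "A3,5,c.pdb,c.csv,2.0", sep = "\n")
  m <- load_manifest(text = txt)
  expect_equal(nrow(m), 3)
  expect_true(all(m$pass))
  expect_equal(m$ec_class, c("EC1", "EC3", "EC5"))

  m2 <- load_manifest(text = paste(
    "structure_id,ec,structure_path,sites_path,resolution",
    "B1,2.1.1.1,a.pdb,a.csv,3.1", sep = "\n"))
  expect_false(m2$pass)
  expect_match(m2$fail_reason, "resolution")

  m3 <- load_manifest(text = paste(
    "structure_id,ec,structure_path,sites_path",
    "C1,7.1.1,a.pdb,a.csv", sep = "\n"))
  expect_false(m3$valid_ec)
  expect_match(m3$fail_reason, "invalid-EC")

  expect_error(load_manifest(text = "structure_id,ec\nX,1"),
               class = "chanatomy_schema_error")
})
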