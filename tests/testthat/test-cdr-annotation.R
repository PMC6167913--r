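test_that("labelled FASTA pairing and phenotype parsing work", {
  set <- generate_antibody_set(seq_gen_config(4, 6, seed = 3))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_antibody_fasta(set, f)
  rt <- read_labelled_fasta(f)
  expect_equal(nrow(rt), 10)
  expect_identical(as.data.frame(rt), as.data.frame(set))
  # duplicate H entry -> pairing error naming the id
  lines <- readLines(f)
  dup <- sub("\\|L\\|", "|H|", lines[grep("^>SYN1\\|L\\|", lines)])
  writeLines(c(lines, dup, "AAAA"), f)
  expect_error(read_labelled_fasta(f), class = "abloopr_pairing_error")
  # unknown phenotype token maps to unknown
  f2 <- withr::local_tempfile(fileext = ".fasta")
  set2 <- set
  set2$phenotype <- "mystery"
  write_antibody_fasta(set2, f2)
  expect_true(all(read_labelled_fasta(f2)$phenotype == "unknown"))
})

test_that("anchor-motif CDR-3 extraction is exact and idempotent", {
  loops <- c("GDYVMDY", "AKDGGYSSGWYVRGF", "VIMHSKNVIM")
  for (loop in loops) {
    h <- paste0("AASLRLSTAVYYCAR", loop, "WGQGTLVTVSS")
    got <- extract_cdr3(h, "H")
    expect_equal(got$loop_seq, loop)
    expect_equal(got$length, nchar(loop))
    expect_equal(substr(h, got$start + 1, got$end), loop)
    l <- paste0("DFTLTISSLQPEDFATYYC", loop, "FGQGTKVEIK")
    expect_equal(extract_cdr3(l, "L")$loop_seq, loop)
  }
  # extracting from framework + extracted loop reproduces the loop
  got <- extract_cdr3(paste0("TAVYYCAR", "GDYW", "WGQGTL"), "H")
  expect_equal(got$loop_seq, "GDYW")
  # missing J motif
  expect_error(extract_cdr3("TAVYYCARGDYVMDY", "H"),
               class = "abloopr_extraction_error")
  # multiple J motifs -> most C-terminal, with a warning
  expect_warning(
    got2 <- extract_cdr3("TAVYYCARAAWGQGDDWGQGTL", "H"),
    "most C-terminal")
  expect_equal(got2$loop_seq, "AAWGQGDD")
})

test_that("Chothia labels carry centre-out insertion codes", {
  # heavy loop of 13: insertions 100A..100E between 100 and 101
  got <- extract_cdr3(paste0("TAVYYCAR", strrep("G", 13), "WGQGTL"), "H")
  expect_equal(got$numbering[[1]],
               c("95", "96", "97", "98", "99", "100", "100A", "100B", "100C",
                 "100D", "100E", "101", "102"))
  # an 8-residue heavy loop needs no insertions
  got8 <- extract_cdr3(paste0("TAVYYCAR", strrep("A", 8), "WGQGTL"), "H")
  expect_equal(got8$numbering[[1]], as.character(95:102))
  # short loops drop base numbers outward from the centre
  got5 <- extract_cdr3(paste0("TAVYYCAR", strrep("A", 5), "WGQGTL"), "H")
  expect_equal(got5$numbering[[1]], c("95", "96", "97", "101", "102"))
  # light chain inserts after 95
  gl <- extract_cdr3(paste0("FATYYC", strrep("A", 11), "FGQGTK"), "L")
  expect_equal(gl$numbering[[1]],
               c("89", "90", "91", "92", "93", "94", "95", "95A", "95B",
                 "96", "97"))
})

test_that("Chothia numbering survives a PDB round trip", {
  labels <- c("95", "96", "100", "100A", "100B", "101", "102")
  resno <- as.integer(sub("[A-Z]$", "", labels))
  insert <- ifelse(grepl("[A-Z]$", labels), sub("^\\d+", "", labels), "")
  bb <- build_ideal_backbone("strand", length(labels))
  atoms <- bb$atoms
  atoms$resno <- rep(resno, each = 4)
  atoms$insert <- rep(insert, each = 4)
  ens <- loop_ensemble(bb$xyz, atoms)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, f)
  back <- read_multimodel_pdb(f)
  got <- unique(paste0(back$atoms$resno, back$atoms$insert))
  expect_equal(got, labels)
})

test_that("length distributions count every record once", {
  set <- generate_antibody_set(seq_gen_config(4, 6, seed = 5))
  ld <- length_distribution(set, "H")
  expect_equal(sum(ld$count), nrow(set))
  expect_s3_class(ld, "cdr_length_distribution")
  # single record puts all mass at its length
  one <- length_distribution(set[1, ], "H")
  expect_equal(nrow(one), 1)
  expect_equal(one$count, 1L)
  # generator length ranges order the means
  long <- generate_antibody_set(seq_gen_config(3, 3, c(18, 25), seed = 7))
  short <- generate_antibody_set(seq_gen_config(3, 3, c(8, 14), seed = 7))
  expect_gt(attr(length_distribution(long, "H"), "mean"),
            attr(length_distribution(short, "H"), "mean"))
  expect_error(length_distribution(set[0, ], "H"),
               class = "abloopr_input_error")
})

test_that("CDR tables survive a TSV round trip", {
  set <- generate_antibody_set(seq_gen_config(2, 2, seed = 9))
  cdrs <- annotate_cdr3(set)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cdr_table(cdrs, f)
  back <- read_cdr_table(f)
  expect_equal(back$loop_seq, cdrs$loop_seq)
  expect_equal(back$numbering, cdrs$numbering)
})
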