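test_that("variant TSV reading filters by depth and errors on malformed lines", {
  tsv <- write_tmp(c(
    "contig\tpos\tref\talt\tref_count\talt_count",
    "c1\t10\tA\tG\t12\t8",
    "c1\t20\tC\tT\t5\t3",
    "c2\t5\tG\tA\t30\t10"), ".tsv")
  x <- read_variant_table(tsv, min_depth = 1)
  expect_equal(nrow(x), 3L)
  expect_equal(x$contig, c("c1", "c1", "c2"))
  expect_equal(x$alt_count, c(8L, 3L, 10L))

  # depth threshold is on ref + alt
  x10 <- read_variant_table(tsv, min_depth = 10)
  expect_equal(nrow(x10), 2L)
  expect_false(any(x10$ref_count + x10$alt_count < 10))

  bad <- write_tmp(c(
    "contig\tpos\tref\talt\tref_count\talt_count",
    "c1\t10\tA\tG\t12\teight"), ".tsv")
  expect_error(read_variant_table(bad), "line 2")
})

test_that("VCF reading keeps biallelic SNVs and the first sample's AD", {
  vcf <- write_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "c1\t10\t.\tA\tG\t.\t.\t.\tGT:AD\t0/1:12,8\t0/1:1,1",
    "c1\t20\t.\tC\tT,G\t.\t.\t.\tGT:AD\t0/1:5,3,2\t0/1:2,2,2",
    "c1\t30\t.\tG\tA\t.\t.\t.\tGT:AD\t0/1:30,10\t0/1:3,3"), ".vcf")
  x <- read_variant_table(vcf, format = "vcf")
  # the triallelic site is excluded
  expect_equal(nrow(x), 2L)
  expect_equal(x$pos, c(10L, 30L))
  # first sample's AD, not the second's
  expect_equal(x$ref_count, c(12L, 30L))
  expect_equal(x$alt_count, c(8L, 10L))

  # a record without AD is skipped with a warning
  vcf2 <- write_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "c1\t10\t.\tA\tG\t.\t.\t.\tGT\t0/1",
    "c1\t30\t.\tG\tA\t.\t.\t.\tGT:AD\t0/1:30,10"), ".vcf")
  expect_warning(x2 <- read_variant_table(vcf2, format = "vcf"), "AD")
  expect_equal(x2$pos, 30L)
})

test_that("variant tables round-trip through TSV", {
  v <- simulate_variants(ploidy_sim_spec("triploid", 200, seed = 11))
  path <- tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  v2 <- read_variant_table(path, min_depth = 1)
  expect_equal(as.data.frame(v2), as.data.frame(v))
})

test_that("hit tables respect the partition map and parse e-values", {
  row <- function(q, s, ev, tax) {
    paste(q, s, "85.0", "100", "10", "1", "1", "100", "1", "100", ev, "180",
          tax, sep = "\t")
  }
  path <- write_tmp(c(row("g1", "p1", "3e-50", "tax_bact"),
                      row("g1", "p2", "1e-10", "tax_worm"),
                      row("g2", "p3", "0.001", "tax_self")), ".tsv")
  pm <- c(tax_bact = "non_metazoan", tax_worm = "metazoan",
          tax_self = "excluded")
  h <- read_hit_table(path, pm)
  expect_equal(nrow(h), 2L)  # self/excluded hit dropped
  expect_equal(h$evalue[1], 3e-50)
  expect_setequal(h$taxon_partition, c("non_metazoan", "metazoan"))

  expect_error(read_hit_table(path, pm[1:2]), "tax_self")

  # 13th column as direct partition label
  path2 <- write_tmp(c(row("g1", "p1", "1e-5", "metazoan")), ".tsv")
  h2 <- read_hit_table(path2)
  expect_equal(h2$taxon_partition, "metazoan")

  # round trip
  out <- tempfile(fileext = ".tsv")
  write_hit_table(h, out)
  h3 <- read_hit_table(out)
  expect_equal(h3$evalue, h$evalue)
  expect_equal(h3$query_id, h$query_id)
  expect_equal(h3$taxon_partition, h$taxon_partition)
})

test_that("gene models carry intron counts and contig co-location", {
  gff <- write_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
    "c1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "c1\tsrc\texon\t1\t100\t.\t+\t.\tParent=g1.t1",
    "c1\tsrc\texon\t201\t300\t.\t+\t.\tParent=g1.t1",
    "c1\tsrc\texon\t401\t500\t.\t+\t.\tParent=g1.t1",
    "c1\tsrc\tgene\t1000\t1900\t.\t-\t.\tID=g2",
    "c1\tsrc\texon\t1000\t1900\t.\t-\t.\tParent=g2",
    "c2\tsrc\tgene\t1\t300\t.\t+\t.\tID=g3",
    "c2\tsrc\texon\t1\t300\t.\t+\t.\tParent=g3"), ".gff3")
  g <- read_gene_models(gff)
  expect_equal(g$intron_count[g$gene_id == "g1"], 2L)
  expect_equal(g$intron_count[g$gene_id == "g2"], 0L)
  # g1 and g2 share a contig, 1-based coordinates preserved
  expect_equal(g$contig[g$gene_id == "g1"], g$contig[g$gene_id == "g2"])
  expect_equal(g$exons[[which(g$gene_id == "g1")]][1, ], c(start = 1L, end = 100L))

  bad <- write_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
    "c1\tsrc\texon\t1\t100\t.\t+\t.\tParent=nothing"), ".gff3")
  expect_error(read_gene_models(bad), "unresolvable")

  # write/read round trip preserves structure
  out <- tempfile(fileext = ".gff3")
  write_gene_models(g, out)
  g2 <- read_gene_models(out)
  expect_equal(g2$intron_count, g$intron_count)
  expect_equal(g2$exons, g$exons)
})

test_that("matrix-shaped inputs round-trip", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2,
              dimnames = list(c("f1", "f2"), c("sp1", "sp2")))
  p <- tempfile(fileext = ".tsv")
  write_presence_matrix(m, p)
  expect_equal(read_presence_matrix(p), m)

  phylip <- write_tmp(c("3", "alpha 0.0 0.1 0.2", "beta 0.1 0.0 0.3",
                        "gamma 0.2 0.3 0.0"), ".phylip")
  dm <- read_distance_matrix(phylip)
  expect_equal(dm["alpha", "gamma"], 0.2)
  expect_true(isSymmetric(dm))

  long <- write_tmp(c("taxon_a\ttaxon_b\tdistance", "x\ty\t0.5", "x\tz\t0.7",
                      "y\tz\t0.2"), ".tsv")
  dml <- read_distance_matrix(long)
  expect_equal(dml["z", "x"], 0.7)
  expect_equal(diag(dml), c(x = 0, y = 0, z = 0))

  e <- tempfile(fileext = ".tsv")
  write_expression(c(gA = 12.5, gB = 0), e)
  expect_equal(read_expression(e), c(gA = 12.5, gB = 0))
})
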