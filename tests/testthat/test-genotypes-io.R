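test_that("ped/map parsing maps letters, populations and missingness", {
  fx <- write_fixture_ped_map()
  d <- read_ped_map(fx$ped, fx$map)

  expect_equal(n_samples(d), 2L)
  expect_equal(n_markers(d), 3L)
  expect_equal(sum(is.na(d$geno)), 1L)
  expect_true(is.na(d$geno["B", "m2"]))
  expect_equal(d$samples$population, c("FAM1", "FAM2"))
  expect_equal(d$markers$chromosome, c("1", "1", "2"))
  expect_equal(d$markers$position, c(100L, 200L, 300L))
  # counted allele = first letter seen in file order
  expect_equal(d$markers$allele1, c("A", "A", "C"))
  expect_equal(d$markers$allele2, c("G", "G", "T"))
  expect_equal(unname(d$geno["A", ]), c(2L, 1L, 2L))
  expect_equal(unname(d$geno["B", ]), c(1L, NA_integer_, 1L))
})

test_that("malformed ped/map input is rejected with a located message", {
  fx <- write_fixture_ped_map()
  bad_ped <- file.path(fx$dir, "bad.ped")
  writeLines(c("FAM1 A 0 0 1 -9 A A A G C C",
               "FAM2 B 0 0 2 -9 A G 0 0 C"), bad_ped)  # 2M + 5 fields
  expect_error(read_ped_map(bad_ped, fx$map), "line 2")

  tri_ped <- file.path(fx$dir, "tri.ped")
  writeLines(c("F1 A 0 0 1 -9 A A", "F2 B 0 0 1 -9 C G"), tri_ped)
  tri_map <- file.path(fx$dir, "tri.map")
  writeLines("1\tmX\t0\t50", tri_map)
  expect_error(read_ped_map(tri_ped, tri_map), "mX")
})

test_that("ped/map and eigenstrat round trips preserve the dataset", {
  fx <- write_fixture_ped_map()
  d <- read_ped_map(fx$ped, fx$map)

  p2 <- file.path(fx$dir, "rt.ped"); m2 <- file.path(fx$dir, "rt.map")
  write_ped_map(d, p2, m2)
  d2 <- read_ped_map(p2, m2)
  expect_equal(unname(d2$geno), unname(d$geno))
  expect_equal(d2$samples$population, d$samples$population)
  expect_equal(d2$markers$position, d$markers$position)
  # second write is byte-identical (stable genotype content)
  p3 <- file.path(fx$dir, "rt2.ped"); m3 <- file.path(fx$dir, "rt2.map")
  write_ped_map(d2, p3, m3)
  expect_identical(readLines(p3), readLines(p2))
  expect_identical(readLines(m3), readLines(m2))

  g <- file.path(fx$dir, "e.geno"); s <- file.path(fx$dir, "e.snp")
  i <- file.path(fx$dir, "e.ind")
  write_eigenstrat(d, g, s, i)
  d3 <- read_eigenstrat(g, s, i)
  expect_equal(unname(d3$geno), unname(d$geno))
  expect_equal(d3$samples$population, d$samples$population)
  expect_equal(d3$markers$allele1, d$markers$allele1)
  g2 <- file.path(fx$dir, "e2.geno")
  write_eigenstrat(d3, g2, file.path(fx$dir, "e2.snp"),
                   file.path(fx$dir, "e2.ind"))
  expect_identical(readLines(g2), readLines(g))
})

test_that("eigenstrat coding table is exact, including all-missing markers", {
  geno <- matrix(c(2L, 1L, 0L, NA,
                   NA, NA, NA, NA), 4, 2)
  d <- make_dataset(geno)
  dir <- fresh_dir()
  paths <- write_eigenstrat(d, file.path(dir, "x.geno"),
                            file.path(dir, "x.snp"), file.path(dir, "x.ind"))
  lines <- readLines(paths$geno)
  expect_equal(lines[1], "2109")
  expect_equal(lines[2], "9999")
  ind <- read.table(paths$ind, stringsAsFactors = FALSE)
  expect_equal(ind$V3, rep("POP1", 4))

  # undefined alleles with non-missing calls cannot be encoded
  d$markers$allele1 <- NA_character_
  expect_error(write_eigenstrat(d, file.path(dir, "y.geno"),
                                file.path(dir, "y.snp"),
                                file.path(dir, "y.ind")),
               "undefined alleles")
})

test_that("hapmap export writes one row per marker with letter genotypes", {
  d <- make_dataset(matrix(c(2L, 1L, 0L, NA), 2, 2))
  path <- file.path(fresh_dir(), "out.hapmap.txt")
  write_hapmap(d, path)
  lines <- readLines(path)
  expect_length(lines, 1L + n_markers(d))
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(fields[1], "m1")
  expect_equal(fields[2], "A/C")
  expect_equal(fields[12:13], c("AA", "AC"))
  fields2 <- strsplit(lines[3], "\t")[[1]]
  expect_equal(fields2[12:13], c("CC", "NN"))
})

test_that("position deduplication merges concordant and drops discordant groups", {
  # m1,m2 duplicate at (1,100) concordant; m3,m4,m5 triplicate at (1,300)
  # concordant; m6,m7 duplicate at (1,600) discordant for sample 1.
  geno <- rbind(c(2L, 2L, 1L, 1L, 1L, 2L, 1L),
                c(0L, NA, 0L, 0L, 0L, 0L, 0L))
  markers <- data.frame(
    id = paste0("m", 1:7), chromosome = "1",
    position = c(100L, 100L, 300L, 300L, 300L, 600L, 600L),
    allele1 = "A", allele2 = "C", stringsAsFactors = FALSE)
  d <- genotype_dataset(geno,
                        data.frame(id = c("s1", "s2"), population = "P"),
                        markers)
  res <- deduplicate_by_position(d)
  expect_equal(res$dataset$markers$id, c("m1", "m3"))
  expect_equal(res$dataset$markers$synonyms, c("m2", "m4;m5"))
  expect_false(anyDuplicated(paste(res$dataset$markers$chromosome,
                                   res$dataset$markers$position)) > 0)
  expect_setequal(res$report$status[res$report$position == 600L],
                  "discordant")
  expect_equal(sort(res$report$status), c("discordant", "merged", "merged"))
})

test_that("deduplication reconciles swapped counted alleles before comparing", {
  # same SNP stored with opposite counted allele: g2 = 2 - g1
  geno <- rbind(c(2L, 0L), c(1L, 1L), c(0L, 2L))
  markers <- data.frame(id = c("a", "b"), chromosome = "1",
                        position = c(5L, 5L),
                        allele1 = c("A", "C"), allele2 = c("C", "A"),
                        stringsAsFactors = FALSE)
  d <- genotype_dataset(geno[, 1:2],
                        data.frame(id = paste0("s", 1:3), population = "P"),
                        markers)
  res <- deduplicate_by_position(d)
  expect_equal(res$report$status, "merged")
  expect_equal(res$dataset$markers$id, "a")
})

test_that("subsetting preserves order and tolerates empty selections", {
  geno <- matrix(1L, 3, 4)
  d <- genotype_dataset(
    geno,
    data.frame(id = c("s1", "s2", "s3"),
               population = c("A", "B", "C")),
    data.frame(id = paste0("m", 1:4),
               chromosome = c("1", "2", "X", "MT"),
               position = 1:4, allele1 = "A", allele2 = "C"))
  s <- subset_dataset(d, populations = c("A", "B"))
  expect_equal(s$samples$id, c("s1", "s2"))
  auto <- subset_dataset(d, location_classes = "autosomal")
  expect_equal(auto$markers$id, c("m1", "m2"))
  empty <- subset_dataset(d, populations = "nope")
  expect_equal(n_samples(empty), 0L)
  expect_equal(n_markers(empty), 4L)
})

test_that("merging keeps shared markers and reconciles allele orientation", {
  ref <- make_dataset(rbind(c(2L, 1L, 0L), c(1L, 1L, 2L)),
                      populations = c("R", "R"), ids = c("r1", "r2"))
  # user shares m2 (same orientation), m3 (swapped alleles), adds m4;
  # user ids must not collide with reference ids
  user_markers <- data.frame(
    id = c("m2", "m3", "m4"), chromosome = "1",
    position = c(200L, 300L, 400L),
    allele1 = c("A", "C", "A"), allele2 = c("C", "A", "G"),
    stringsAsFactors = FALSE)
  user <- genotype_dataset(rbind(c(2L, 0L, 1L)),
                           data.frame(id = "u1", population = "U"),
                           user_markers)
  res <- merge_on_shared_markers(user, ref)
  merged <- res$dataset
  expect_equal(merged$markers$id, c("m2", "m3"))
  expect_equal(merged$samples$id, c("r1", "r2", "u1"))
  expect_equal(unname(merged$geno["u1", ]), c(2L, 2L))  # m3 flipped 0 -> 2

  # symmetry of the shared-marker set in argument order
  res_rev <- merge_on_shared_markers(ref, user)
  expect_setequal(res_rev$dataset$markers$id, merged$markers$id)

  # synonym-only match still links the marker
  syn_ref <- ref
  syn_ref$markers$id[1] <- "chipA_1"
  syn_ref$markers$synonyms[1] <- "m1"
  user_m1 <- make_dataset(rbind(c(2L)), ids = "u9", populations = "U")
  expect_equal(
    merge_on_shared_markers(user_m1, syn_ref)$dataset$markers$id,
    "chipA_1")

  # zero shared markers is an explicit error
  lonely <- genotype_dataset(
    rbind(2L), data.frame(id = "u2", population = "U"),
    data.frame(id = "zzz", chromosome = "9", position = 1L,
               allele1 = "A", allele2 = "C"))
  expect_error(merge_on_shared_markers(lonely, ref), "no markers shared")
})

test_that("strand-ambiguous pairs with mismatched letters are dropped, not guessed", {
  ref <- genotype_dataset(
    rbind(c(2L, 2L)), data.frame(id = "r1", population = "R"),
    data.frame(id = c("m1", "m2"), chromosome = "1", position = c(1L, 2L),
               allele1 = c("A", "A"), allele2 = c("T", "G")))
  user <- genotype_dataset(
    rbind(c(0L, 0L)), data.frame(id = "u1", population = "U"),
    data.frame(id = c("m1", "m2"), chromosome = "1", position = c(1L, 2L),
               allele1 = c("C", "T"), allele2 = c("G", "C")))
  res <- merge_on_shared_markers(user, ref)
  # m1: ref A/T vs user C/G cannot be reconciled (ambiguous pair);
  # m2: ref A/G vs user T/C is a clean strand flip (T->A counted)
  expect_equal(res$dropped$user_id, "m1")
  expect_equal(res$dataset$markers$id, "m2")
  expect_equal(unname(res$dataset$geno["u1", ]), 0L)
})
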