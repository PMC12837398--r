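make_sg <- function(rows, species = "Testocetus unitus") {
  structure(list(species = species, rows = rows, boundaries = NULL),
            class = "supergene_alignment")
}

random_variant_table <- function(n_rec = 6, n_sites = 20, p_missing = 0.1) {
  rows <- replicate(n_rec, paste(
    sample(c("A", "C", "G", "T", "N", "-"), n_sites, replace = TRUE,
           prob = c(rep((1 - p_missing) / 4, 4), p_missing / 2,
                    p_missing / 2)),
    collapse = ""))
  names(rows) <- sprintf("r%02d", seq_len(n_rec))
  variable_sites(make_sg(rows))
}

test_that("variable_sites keeps only polymorphic columns", {
  # identical rows: empty table
  vt0 <- variable_sites(make_sg(c(a = "ACGT", b = "ACGT", c = "ACGT",
                                  d = "ACGT")))
  expect_length(vt0$positions, 0L)
  # one A/A/G/A column
  vt1 <- variable_sites(make_sg(c(a = "AC", b = "AC", c = "GC", d = "AC")))
  expect_identical(vt1$positions, 0L)
  expect_identical(vt1$ref, "A")
  expect_identical(vt1$alt[[1]], "G")
  # gap treated as missing, not as an allele
  vt2 <- variable_sites(make_sg(c(a = "A", b = "-", c = "G")))
  expect_length(vt2$positions, 1L)
  expect_true(is.na(vt2$calls["b", 1]))
  # a column variable only because of a gap is not a site
  vt3 <- variable_sites(make_sg(c(a = "A", b = "-", c = "A")))
  expect_length(vt3$positions, 0L)
})

test_that("VCF round-trips variant tables identically", {
  set.seed(11)
  for (rep in 1:5) {
    vt <- random_variant_table()
    path <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(vt, path)
    back <- read_vcf(path)
    expect_identical(back$positions, vt$positions)
    expect_identical(back$ref, vt$ref)
    expect_identical(back$alt, vt$alt)
    expect_identical(back$calls, vt$calls)
  }
})

test_that("VCF dialect: 1-based positions and lexicographic multi-allelics", {
  rows <- c(a = strrep("A", 100), b = strrep("A", 100),
            c = paste0(strrep("A", 99), "G"))
  vt <- variable_sites(make_sg(rows))
  expect_identical(vt$positions, 99L)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  rec <- grep("^supergene", readLines(path), value = TRUE)
  expect_identical(strsplit(rec, "\t")[[1]][2], "100")
  # tri-allelic site with ref A
  vt3 <- variable_sites(make_sg(c(a = "A", b = "A", c = "C", d = "T")))
  expect_identical(vt3$ref, "A")
  expect_identical(vt3$alt[[1]], c("C", "T"))
  path3 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt3, path3)
  rec3 <- strsplit(grep("^supergene", readLines(path3), value = TRUE),
                   "\t")[[1]]
  expect_identical(rec3[5], "C,T")
  expect_identical(rec3[10:13], c("0", "0", "1", "2"))
  back <- read_vcf(path3)
  expect_identical(back$calls, vt3$calls)
})

test_that("IBS distances equal the brute-force double loop", {
  # definitional examples
  vt <- variable_sites(make_sg(c(
    a = "AAAAAAAAAA", b = "AAAAAAAGGG", c = "AAAAAAAAAA")))
  D <- ibs_distance(vt)
  expect_identical(D["a", "c"], 0)
  expect_equal(D["a", "b"], 1)  # 3 of 3 variable sites differ
  set.seed(5)
  for (rep in 1:10) {
    vt <- random_variant_table(6, 20)
    if (length(vt$positions) == 0) next
    expect_equal(suppressWarnings(ibs_distance(vt)),
                 {
                   d <- naive_ibs(vt$calls)
                   d[is.na(d)] <- max(d, na.rm = TRUE)
                   d
                 },
                 tolerance = 1e-12)
  }
})

test_that("records differing at 3 of 10 shared sites have distance 0.3", {
  calls <- rbind(r1 = c(rep("A", 10)),
                 r2 = c(rep("A", 7), rep("G", 3)),
                 r3 = rep("G", 10))
  vt <- structure(list(positions = 0:9, ref = rep("A", 10),
                       alt = replicate(10, "G", simplify = FALSE),
                       calls = calls, meta = list()),
                  class = "variant_table")
  expect_equal(ibs_distance(vt)["r1", "r2"], 0.3)
})

test_that("zero-overlap pairs get the matrix maximum with a warning", {
  calls <- rbind(r1 = c("A", NA), r2 = c(NA, "C"), r3 = c("G", "T"))
  vt <- structure(list(positions = 0:1, ref = c("A", "C"),
                       alt = list("G", "T"), calls = calls, meta = list()),
                  class = "variant_table")
  expect_warning(D <- ibs_distance(vt), "no overlapping sites")
  expect_identical(D["r1", "r2"], max(D))
  expect_false(anyNA(D))
})

test_that("classical MDS satisfies the Torgerson identities", {
  # 3 equidistant points embed equidistantly
  D <- matrix(1, 3, 3) - diag(3)
  emb <- classical_mds(D, k = 2)
  pd <- as.matrix(dist(emb$points))
  off <- pd[upper.tri(pd)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-12)
  # Euclidean-consistent matrices are reconstructed exactly
  set.seed(33)
  pts <- matrix(rnorm(20), ncol = 2)
  D2 <- as.matrix(dist(pts))
  emb2 <- classical_mds(D2, k = 2)
  expect_equal(as.matrix(dist(emb2$points)), D2, tolerance = 1e-9,
               ignore_attr = TRUE)
  # agreement with the stats reference implementation
  ref <- stats::cmdscale(D2, k = 2)
  expect_equal(abs(emb2$points), abs(ref), tolerance = 1e-9,
               ignore_attr = TRUE)
  # eigenvalues descending, coordinates centered
  expect_true(all(diff(emb2$eigenvalues) <= 1e-9))
  expect_equal(colMeans(emb2$points), c(0, 0), tolerance = 1e-12)
})

test_that("MDS separates two tight blocks on the first axis", {
  D <- rbind(cbind(matrix(0.01, 4, 4), matrix(1, 4, 4)),
             cbind(matrix(1, 4, 4), matrix(0.01, 4, 4)))
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("r", 1:8)
  emb <- suppressWarnings(classical_mds(D, k = 2))
  ax1 <- emb$points[, 1]
  expect_true(max(ax1[1:4]) < min(ax1[5:8]) ||
                min(ax1[1:4]) > max(ax1[5:8]))
})

test_that("k exceeding the positive eigenvalue count pads with zeros", {
  D <- matrix(1, 3, 3) - diag(3)
  rownames(D) <- colnames(D) <- paste0("r", 1:3)
  emb <- classical_mds(D, k = 3)
  expect_true(attr(emb, "padded"))
  expect_equal(emb$points[, 3], c(0, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("population assignment gates on silhouette", {
  set.seed(99)
  # single tight blob: k = 1, no exclusions
  blob <- matrix(rnorm(30, sd = 0.05), ncol = 2,
                 dimnames = list(sprintf("b%02d", 1:15), NULL))
  emb1 <- structure(list(points = blob, eigenvalues = c(1, 1)),
                    class = "mds_embedding")
  asg1 <- assign_populations(emb1, seed = 3)
  expect_identical(attr(asg1, "k"), 1L)
  expect_identical(unique(asg1$population), "Pop1")
  expect_false(any(asg1$excluded))
  # two separated blocks: k = 2, perfect split
  pts <- rbind(matrix(rnorm(20, mean = 0, sd = 0.05), ncol = 2),
               matrix(rnorm(20, mean = 3, sd = 0.05), ncol = 2))
  rownames(pts) <- sprintf("p%02d", 1:20)
  emb2 <- structure(list(points = pts, eigenvalues = c(1, 1)),
                    class = "mds_embedding")
  asg2 <- assign_populations(emb2, seed = 3)
  expect_identical(attr(asg2, "k"), 2L)
  expect_identical(length(unique(asg2$population[1:10])), 1L)
  expect_identical(length(unique(asg2$population[11:20])), 1L)
  expect_false(asg2$population[1] == asg2$population[11])
  # a midpoint record between the demes is excluded as intermediate
  pts3 <- rbind(pts, mid = c(1.5, mean(pts[, 2])))
  emb3 <- structure(list(points = pts3, eigenvalues = c(1, 1)),
                    class = "mds_embedding")
  asg3 <- assign_populations(emb3, seed = 3)
  expect_identical(asg3$population[asg3$record_id == "mid"], "EXCLUDED")
  expect_true(all(asg3$population[asg3$record_id != "mid"] != "EXCLUDED"))
})

test_that("assignment is deterministic and honours overrides", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(16, 0, 0.1), ncol = 2),
               matrix(rnorm(16, 4, 0.1), ncol = 2))
  rownames(pts) <- sprintf("s%02d", 1:16)
  emb <- structure(list(points = pts, eigenvalues = c(1, 1)),
                   class = "mds_embedding")
  a1 <- assign_populations(emb, seed = 21)
  a2 <- assign_populations(emb, seed = 21)
  expect_identical(a1, a2)
  ov <- data.frame(record_id = c("s01", "s16"),
                   population = c("PopX", "EXCLUDED"))
  a3 <- assign_populations(emb, overrides = ov, seed = 21)
  expect_identical(a3$population[a3$record_id == "s01"], "PopX")
  expect_true(a3$excluded[a3$record_id == "s16"])
  expect_error(assign_populations(
    emb, overrides = data.frame(record_id = "zz", population = "Pop1"),
    seed = 21), "unknown record ids")
})
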