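test_that("OR cells parse in combined and split layouts, en-dash or hyphen", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "disease_name,or_ci,direction,source,significant",
    "Glioma,\"5.27 (3.15–8.81)\",per_sd_longer,meta,TRUE",
    "ILD,\"11.11 (6.67-20.00)\",per_sd_shorter,meta,TRUE"), tf)
  a <- readOrTable(tf)
  expect_equal(a$or_per_sd, c(5.27, 11.11))
  expect_equal(a$ci_lower, c(3.15, 6.67))
  expect_equal(a$ci_upper, c(8.81, 20.00))

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "disease_name,or_per_sd,ci_lower,ci_upper,direction",
    "Glioma,5.27,3.15,8.81,per_sd_longer"), tf2)
  expect_equal(readOrTable(tf2)$or_per_sd, 5.27)
})

test_that("malformed OR cells and inverted CIs are rejected with the row named", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("disease_name,or_ci,direction",
               "Glioma,\"5.27 3.15-8.81\",per_sd_longer"), tf)
  expect_error(readOrTable(tf), "Glioma")

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("disease_name,or_per_sd,ci_lower,ci_upper,direction",
               "Glioma,5.27,8.81,3.15,per_sd_longer"), tf2)
  expect_error(readOrTable(tf2), "inverted CI.*Glioma")
})

test_that("an empty association file yields an empty validated table", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines("disease_name,or_per_sd,ci_lower,ci_upper,direction", tf)
  expect_identical(nrow(readOrTable(tf)), 0L)
})

test_that("association and burden tables round-trip through write/read", {
  a <- randomAssocTable(20, seed = 7)
  tf <- withr::local_tempfile(fileext = ".csv")
  writeOrTable(a, tf)
  expect_equal(readOrTable(tf), a, tolerance = 1e-12)

  b <- rbind(makeBurden("x", "incidence", 190.81, 171.96, 211.00),
             makeBurden("x", "daly", 2106.22, 2060.06, 2167.79),
             makeBurden("y", "incidence", 0.012, 0.010, 0.013))
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeBurdenTable(b, tf2)
  expect_equal(readBurdenTable(tf2), b, tolerance = 1e-12)
})

test_that("burden parsing strips thousands separators and keeps NA missing", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cause_name,measure,value,ci_lower,ci_upper,population,year",
               "CHD,daly,\"2,106.22\",\"2,060.06\",\"2,167.79\",Europe,2017",
               "Aortic aneurysm,incidence,NA,NA,NA,Europe,2017"), tf)
  b <- readBurdenTable(tf)
  expect_equal(b$value, c(2106.22, NA))
  expect_equal(b$ci_upper, c(2167.79, NA))
})

test_that("gbd_results dialect maps columns and rejects unknown measures", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("measure,location,sex,age,cause,metric,year,val,upper,lower",
    "Incidence,Europe,Both,Age-standardized,Glioma,Rate,2017,8.39,9.30,7.29",
    paste0("DALYs (Disability-Adjusted Life Years),Europe,Both,",
           "Age-standardized,Glioma,Rate,2017,134.46,150.86,119.42")), tf)
  b <- readBurdenTable(tf, dialect = "gbd_results")
  expect_equal(b$measure, c("incidence", "daly"))
  expect_equal(b$value, c(8.39, 134.46))
  expect_equal(b$population, c("Europe", "Europe"))

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("measure,location,sex,age,cause,metric,year,val,upper,lower",
    "Prevalence,Europe,Both,Age-standardized,Glioma,Rate,2017,1,2,0.5"), tf2)
  expect_error(readBurdenTable(tf2, dialect = "gbd_results"),
               "unknown measure")
})

test_that("negative rates are rejected", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cause_name,measure,value,ci_lower,ci_upper",
               "x,incidence,-1,-2,0"), tf)
  expect_error(readBurdenTable(tf), "negative")
})

test_that("LD matrices read symmetric, mirror triangular input, keep NA", {
  chr2 <- readLdMatrix(fixturePath("ld", "chr2.csv"), chromosome = "2")
  expect_s4_class(chr2, "LDMatrix")
  expect_equal(ldValues(chr2)["rs11125529", "rs11890390"], 0.951)

  # triangular input mirrors to the same matrix as the full fixture
  full <- ldValues(chr2)
  tri <- full; tri[upper.tri(tri)] <- NA
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(RS_number = rownames(tri), tri, check.names = FALSE),
            tf, row.names = FALSE, quote = FALSE)
  expect_equal(ldValues(readLdMatrix(tf, chromosome = "2")), full)

  # a 1x1 matrix is valid with unit diagonal
  tf1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("RS_number,rsX", "rsX,1"), tf1)
  expect_equal(dim(ldValues(readLdMatrix(tf1))), c(1L, 1L))

  # the unmeasured chromosome-8 variant keeps MISSING entries
  chr8 <- readLdMatrix(fixturePath("ld", "chr8.csv"), chromosome = "8")
  expect_true(all(is.na(ldValues(chr8)["rs28365964", ])))
})

test_that("non-square, out-of-range and asymmetric LD inputs error", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("RS_number,rs1,rs2", "rs1,1,0.5"), tf)
  expect_error(readLdMatrix(tf), "not square")

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("RS_number,rs1,rs2", "rs1,1,1.5", "rs2,1.5,1"), tf2)
  expect_error(readLdMatrix(tf2), "\\[0, 1\\]")

  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("RS_number,rs1,rs2", "rs1,1,0.2", "rs2,0.9,1"), tf3)
  expect_error(readLdMatrix(tf3), "asymmetric")
})

test_that("SNP tables validate rsid uniqueness and frequency range", {
  snps <- readSnpTable(fixturePath("snp_panel.csv"))
  expect_true(all(snps$position > 0))

  tf <- withr::local_tempfile(fileext = ".csv")
  writeSnpTable(snps, tf)
  expect_equal(readSnpTable(tf), snps, tolerance = 1e-12)

  bad <- snps[c(1, 1), ]
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, tf2, row.names = FALSE)
  expect_error(readSnpTable(tf2), "duplicate rsid.*rs621559")

  bad2 <- snps[1, ]; bad2$short_allele_freq <- 1.2
  tf3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad2, tf3, row.names = FALSE)
  expect_error(readSnpTable(tf3), "frequency")
})

test_that("excess tables round-trip and carry a 2-decimal display column", {
  rows <- excessBurden(makeAssoc("Glioma", 5.27, 3.15, 8.81),
                       makeBurden("Glioma", "incidence", 8.39, 7.29, 9.30))
  tf <- withr::local_tempfile(fileext = ".csv")
  writeExcessTable(rows, tf)
  back <- readExcessTable(tf)
  expect_equal(back$value, rows$value, tolerance = 1e-12)
  raw <- read.csv(tf)
  expect_match(raw$display[1], "^35\\.83 ")
})
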