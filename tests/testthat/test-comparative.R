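test_that("tooth aspect ratio follows the reference worked examples", {
  expect_equal(round_half_out(aspect_ratio(11.9, 2.2), 1), 0.2)
  expect_equal(round_half_out(aspect_ratio(8.4, 5.6), 1), 0.7)
  expect_equal(aspect_ratio(3, 3), 1)
  expect_error(aspect_ratio(0, 2), "length")
})

test_that("dentition summary reproduces the reference table", {
  teeth <- tooth_measurements()
  ar <- round_half_out(aspect_ratio(teeth$length_mm, teeth$diameter_mm), 1)
  # reference per-tooth aspect ratios; the printed table's sixth gracile
  # cell (0.5) is inconsistent with its own measurements (2.8/7.2 -> 0.4)
  # and is asserted at the arithmetically correct value
  expect_equal(ar[teeth$specimen == "M1409"],
               c(0.2, 0.4, 0.3, 0.2, 0.2, 0.2, 0.2, 0.7, 0.3, 0.2))
  expect_equal(ar[teeth$specimen == "M1399"],
               c(0.5, 0.3, 0.3, 0.4, 0.4, 0.4, 0.3, 0.3, 0.5, 0.3))

  ds <- dentition_summary(teeth)
  rob <- ds[ds$specimen == "M1409", ]
  gra <- ds[ds$specimen == "M1399", ]
  expect_equal(rob$mean_length_rounded, 9.6)
  expect_equal(rob$mean_diameter_rounded, 2.6)
  expect_equal(rob$mean_aspect_rounded, 0.3)
  expect_equal(gra$mean_length_rounded, 7.2)
  # the printed gracile mean diameter (2.7) is inconsistent with the ten
  # printed diameters, which sum to 26.1: the arithmetic mean is 2.61
  expect_equal(gra$mean_diameter_rounded, 2.6)
  expect_equal(gra$mean_aspect_rounded, 0.4)

  # single tooth: means equal the tooth's own values
  one <- data.frame(specimen = "x", tooth = 1, length_mm = 5,
                    diameter_mm = 2)
  d1 <- dentition_summary(one)
  expect_equal(d1$mean_length_mm, 5)
  expect_equal(d1$mean_aspect_ratio, 0.4)
  # unlabelled mixed measurements are an error
  expect_error(dentition_summary(data.frame(length_mm = 1,
                                            diameter_mm = 1)),
               "specimen")
})

make_summary <- function(nasal, rostrum, volume = c(10, 30)) {
  data.frame(region = c("nasal", "rostrum"), n = c(5, 5),
             excluded = c(0, 0), volume = volume,
             mean = c(nasal, rostrum), median = c(nasal, rostrum),
             p95 = c(nasal, rostrum), max = c(nasal, rostrum))
}

test_that("stress contrast: identities, scaling invariance, verdicts", {
  sums <- list(
    "gracile:bite_posterior" = make_summary(0.1, 0.2),
    "gracile:bite_mid" = make_summary(0.4, 0.3),
    "gracile:bite_anterior" = make_summary(0.3, 0.35),
    "robust:bite_posterior" = make_summary(0.1, 0.1),
    "robust:bite_mid" = make_summary(0.12, 0.11))
  ct <- stress_contrast(sums)
  expect_equal(unname(ct$shift_index["gracile"]), (0.4 - 0.1) / 0.1)
  expect_equal(unname(ct$shift_index["robust"]), 0.2)
  expect_true(all(ct$verdicts))

  # identical fields for both positions give shift index zero
  sums0 <- sums
  sums0[["gracile:bite_mid"]] <- sums0[["gracile:bite_posterior"]]
  ct0 <- stress_contrast(sums0)
  expect_equal(unname(ct0$shift_index["gracile"]), 0)

  # scaling every stress by a constant leaves ratios and shifts unchanged
  sums_c <- lapply(sums, function(s) {
    s[c("mean", "median", "p95", "max")] <-
      s[c("mean", "median", "p95", "max")] * 7
    s
  })
  ct_c <- stress_contrast(sums_c)
  expect_equal(ct_c$shift_index, ct$shift_index)
  expect_equal(ct_c$rostrum_nasal_ratio, ct$rostrum_nasal_ratio)

  # missing load case errors with the required labels
  expect_error(stress_contrast(sums[-2]), "gracile:bite_mid")
})

test_that("report generation is complete, gap-aware and deterministic", {
  dims <- muscle_dimensions()
  results <- list(
    muscle_tables = list(M1409 = muscle_force_table("M1409", dims)),
    dentition = dentition_summary(),
    provenance = list(config_hash = "abc", seed = 1))
  d1 <- file.path(tempdir(), "rep1")
  r1 <- generate_report(results, d1)
  expect_equal(r1$status, 1L) # stress sections absent -> nonzero status
  expect_true(any(grepl("Missing sections",
                        readLines(file.path(d1, "report.md")))))
  expect_true(file.exists(file.path(d1, "muscle_forces_M1409.csv")))

  # determinism: identical inputs give byte-identical numeric tables
  d2 <- file.path(tempdir(), "rep2")
  generate_report(results, d2)
  f1 <- readLines(file.path(d1, "muscle_forces_M1409.csv"))
  f2 <- readLines(file.path(d2, "muscle_forces_M1409.csv"))
  expect_identical(f1, f2)
})
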