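test_that("depth filter requires every member at or above the threshold", {
  cfg <- filter_config()
  g <- dplyr::bind_rows(
    gt_row(pos = 1, proband_dp = 30, father_dp = 12, mother_dp = 8),
    gt_row(pos = 2, proband_dp = 30, father_dp = 12, mother_dp = 7),
    gt_row(pos = 3, proband_dp = 30, father_dp = NA, mother_dp = 12)
  )
  expect_equal(passes_depth(g, cfg), c(TRUE, FALSE, FALSE))
})

test_that("rarity is strict and treats undocumented variants as rare", {
  cfg <- filter_config()
  expect_equal(is_rare(c(5.01e-5, NA, 0.001, 0.0009999), cfg),
               c(TRUE, TRUE, FALSE, TRUE))
})

test_that("variant classes follow the consequence/CADD rules with strict boundaries", {
  cfg <- filter_config()
  v <- dplyr::bind_rows(
    ann_row(pos = 1, consequence = "missense", cadd = 26.5),
    ann_row(pos = 2, consequence = "stopgain", cadd = NA),
    ann_row(pos = 3, consequence = "missense", cadd = 20.0),
    ann_row(pos = 4, consequence = "missense", cadd = NA),
    ann_row(pos = 5, consequence = "frameshift", cadd = 5),
    ann_row(pos = 6, consequence = "synonymous", cadd = 35)
  )
  got <- classify_variants(v, cfg)$variant_class
  expect_equal(got, c("DNS", "LOF", "NEITHER", "NEITHER", "LOF", "NEITHER"))
})

test_that("stoploss is LOF by default but the class set is overridable", {
  v <- ann_row(consequence = "stoploss", cadd = NA)
  expect_equal(classify_variants(v, filter_config())$variant_class, "LOF")
  narrow <- filter_config(lof_classes = c("stopgain", "frameshift",
                                          "splicing"))
  expect_equal(classify_variants(v, narrow)$variant_class, "NEITHER")
})

test_that("DNS/LOF/NEITHER partition every variant", {
  cfg <- filter_config()
  set.seed(42)
  v <- ann_row(pos = 1:400)[rep(1, 400), ] |>
    dplyr::mutate(
      pos = 1:400,
      consequence = sample(c("missense", "stopgain", "stoploss", "frameshift",
                             "splicing", "synonymous", "other"),
                           400, replace = TRUE),
      cadd = ifelse(runif(400) < 0.2, NA, runif(400, 0, 40))
    )
  cls <- classify_variants(v, cfg)$variant_class
  expect_true(all(cls %in% c("DNS", "LOF", "NEITHER")))
  # missense is never LOF; LOF classes are never DNS
  expect_false(any(cls == "LOF" & v$consequence == "missense"))
  expect_false(any(cls == "DNS" & v$consequence != "missense"))
})

test_that("rare and DNS sets are monotone in their thresholds", {
  set.seed(7)
  af <- ifelse(runif(300) < 0.3, NA, runif(300, 0, 0.01))
  v <- ann_row(pos = 1:300)[rep(1, 300), ] |>
    dplyr::mutate(pos = 1:300, consequence = "missense",
                  cadd = runif(300, 0, 40), af_ref = af)
  for (pair in list(c(1e-4, 1e-3), c(1e-3, 5e-3))) {
    lo <- which(is_rare(v$af_ref, filter_config(af_threshold = pair[1])))
    hi <- which(is_rare(v$af_ref, filter_config(af_threshold = pair[2])))
    expect_true(all(lo %in% hi))
  }
  for (pair in list(c(10, 20), c(20, 30))) {
    hi <- which(classify_variants(v, filter_config(cadd_threshold = pair[1]))$variant_class == "DNS")
    lo <- which(classify_variants(v, filter_config(cadd_threshold = pair[2]))$variant_class == "DNS")
    expect_true(all(lo %in% hi))
  }
})

test_that("cascade counts match a brute-force one-pass oracle", {
  cfg <- filter_config()
  # planted composition: 10 rare DNS + 5 rare LOF among 100 common variants
  v <- dplyr::bind_rows(
    ann_row(pos = 1:10)[rep(1, 10), ] |>
      dplyr::mutate(pos = 1:10, consequence = "missense", cadd = 30,
                    af_ref = NA_real_),
    ann_row(pos = 11:15)[rep(1, 5), ] |>
      dplyr::mutate(pos = 11:15, consequence = "stopgain", cadd = NA,
                    af_ref = 1e-5),
    ann_row(pos = 16:115)[rep(1, 100), ] |>
      dplyr::mutate(pos = 16:115, consequence = "missense", cadd = 30,
                    af_ref = 0.05)
  )
  got <- cascade_counts(v, cfg)
  expect_equal(unlist(got[1, ]),
               c(total = 115, rare = 15, rare_deleterious = 15,
                 rare_dns = 10, rare_lof = 5))

  # independent oracle: explicit loop over rows
  oracle <- function(v, cfg) {
    tot <- 0; rare <- 0; dns <- 0; lof <- 0
    for (i in seq_len(nrow(v))) {
      tot <- tot + 1
      r <- is.na(v$af_ref[i]) || v$af_ref[i] < cfg$af_threshold
      if (!r) next
      rare <- rare + 1
      if (v$consequence[i] %in% cfg$lof_classes) {
        lof <- lof + 1
      } else if (v$consequence[i] == "missense" && !is.na(v$cadd[i]) &&
                 v$cadd[i] > cfg$cadd_threshold) {
        dns <- dns + 1
      }
    }
    c(total = tot, rare = rare, rare_deleterious = dns + lof,
      rare_dns = dns, rare_lof = lof)
  }
  set.seed(99)
  for (k in 1:5) {
    n <- 500
    vv <- ann_row(pos = 1:n)[rep(1, n), ] |>
      dplyr::mutate(
        pos = 1:n,
        consequence = sample(c("missense", "stopgain", "frameshift",
                               "splicing", "stoploss", "synonymous"),
                             n, replace = TRUE),
        cadd = ifelse(runif(n) < 0.2, NA, runif(n, 0, 40)),
        af_ref = ifelse(runif(n) < 0.3, NA, runif(n, 0, 0.01))
      )
    expect_equal(unlist(cascade_counts(vv, cfg)[1, ]), oracle(vv, cfg))
  }
})

test_that("cascade tallies are internally consistent and empty input is all zeros", {
  z <- cascade_counts(ann_row()[0, ])
  expect_equal(unlist(z[1, ]),
               c(total = 0, rare = 0, rare_deleterious = 0, rare_dns = 0,
                 rare_lof = 0))
  co <- generate_cohort(small_spec(seed = 5))
  cc <- cascade_counts(co$annotation)
  expect_equal(cc$rare_deleterious, cc$rare_dns + cc$rare_lof)
  expect_lte(cc$rare_deleterious, cc$rare)
  expect_lte(cc$rare, cc$total)
})

test_that("filter_cascade drops low-depth, common and unclassed records", {
  g <- dplyr::bind_rows(
    gt_row(pos = 1),                      # rare DNS, good depth -> kept
    gt_row(pos = 2, father_dp = 3),       # fails depth
    gt_row(pos = 3),                      # common -> dropped
    gt_row(pos = 4)                       # synonymous -> dropped
  )
  ann <- dplyr::bind_rows(
    ann_row(pos = 1, cadd = 30),
    ann_row(pos = 2, cadd = 30),
    ann_row(pos = 3, cadd = 30, af_ref = 0.05),
    ann_row(pos = 4, consequence = "synonymous")
  )
  out <- filter_cascade(g, ann)
  expect_equal(out$pos, 1L)
  expect_equal(out$variant_class, "DNS")
})
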