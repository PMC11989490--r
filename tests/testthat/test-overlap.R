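mk_vec <- function(id, pid, date, values) {
  list(report_id = id, patient_id = pid, report_date = as.Date(date),
       values = values, af_new_onset = NA, af_prior_history = NA)
}
lab_map <- c(creatinine = "lab", lvef = "echo", diabetes = "history")

test_that("temporal windows admit and reject values per variable class", {
  debut <- as.Date("2019-06-01")
  # lab 210 days before debut: outside the 180-day window -> missing
  v1 <- mk_vec("A-R1", "A", debut - 210, list(creatinine = 1.5))
  pv <- merge_patient(list(v1), debut, overlap_config(), lab_map)
  expect_null(pv$values$creatinine)
  # 10-day value beats 30-day value
  v2 <- mk_vec("A-R2", "A", debut - 30, list(creatinine = 2.0))
  v3 <- mk_vec("A-R3", "A", debut - 10, list(creatinine = 1.1))
  pv <- merge_patient(list(v1, v2, v3), debut, overlap_config(), lab_map)
  expect_equal(pv$values$creatinine, 1.1)
  expect_equal(pv$source$creatinine$days_from_debut, -10)
  # echo 60 days after debut is inside its symmetric 90-day window
  v4 <- mk_vec("A-R4", "A", debut + 60, list(lvef = 55))
  pv <- merge_patient(list(v4), debut, overlap_config(), lab_map)
  expect_equal(pv$values$lvef, 55)
  # but a lab value after debut is rejected (window_after = 0)
  v5 <- mk_vec("A-R5", "A", debut + 5, list(creatinine = 1.8))
  pv <- merge_patient(list(v5), debut, overlap_config(), lab_map)
  expect_null(pv$values$creatinine)
  # history uses an unbounded window before debut
  v6 <- mk_vec("A-R6", "A", debut - 2000, list(diabetes = TRUE))
  pv <- merge_patient(list(v6), debut, overlap_config(), lab_map)
  expect_true(pv$values$diabetes)
})

test_that("ties at equal distance resolve to earlier report then id", {
  debut <- as.Date("2019-06-01")
  before <- mk_vec("A-R1", "A", debut - 30, list(lvef = 40))
  after <- mk_vec("A-R2", "A", debut + 30, list(lvef = 60))
  pv <- merge_patient(list(after, before), debut, overlap_config(),
                      lab_map)
  expect_equal(pv$values$lvef, 40)  # earlier report wins the tie
  same_day_b <- mk_vec("A-R0", "A", debut - 30, list(lvef = 35))
  pv <- merge_patient(list(before, same_day_b), debut, overlap_config(),
                      lab_map)
  expect_equal(pv$values$lvef, 35)  # smaller report id wins
})

test_that("input contracts: multi-patient error, empty list all-missing", {
  a <- mk_vec("A-R1", "A", "2019-01-01", list(creatinine = 1))
  b <- mk_vec("B-R1", "B", "2019-01-01", list(creatinine = 1))
  expect_error(merge_patient(list(a, b), "2019-06-01"), "input error")
  pv <- merge_patient(list(), "2019-06-01", overlap_config(), lab_map)
  expect_length(pv$values, 0L)
  expect_equal(pv$missing_count, length(lab_map))
})

test_that("merge is invariant under permutation of the input vectors", {
  vecs <- random_timeline("P1", 6, names(lab_map), seed = 5)
  debut <- as.Date("2018-06-01")
  ref <- merge_patient(vecs, debut, overlap_config(), lab_map)
  with_seed(6, {
    for (i in 1:10) {
      perm <- sample(vecs)
      pv <- merge_patient(perm, debut, overlap_config(), lab_map)
      expect_identical(pv$values, ref$values)
      expect_identical(pv$source, ref$source)
    }
  })
})

test_that("merged choices equal the brute-force nearest-candidate scan", {
  cfg <- overlap_config()
  windows <- list(lab = c(180, 0), echo = c(90, 90), history = c(Inf, 0))
  with_seed(31, {
    for (i in 1:120) {
      vecs <- random_timeline(sprintf("P%03d", i), sample(1:6, 1),
                              names(lab_map), seed = 1000 + i)
      debut <- as.Date("2018-06-01")
      pv <- merge_patient(vecs, debut, cfg, lab_map)
      for (vid in names(lab_map)) {
        w <- windows[[lab_map[[vid]]]]
        want <- oracle_merge_value(vecs, vid, debut, w[1], w[2])
        if (is.null(want)) {
          expect_null(pv$values[[vid]])
        } else {
          expect_equal(pv$values[[vid]], want$value)
          expect_equal(pv$source[[vid]]$report_id, want$id)
        }
        # window soundness of whatever was chosen
        if (!is.null(pv$source[[vid]])) {
          d <- pv$source[[vid]]$days_from_debut
          expect_true(d >= -w[1] && d <= w[2])
        }
      }
    }
  })
})

test_that("resolve_debut honors earlier prior-history assertions", {
  mk <- function(id, date, onset, prior) {
    v <- mk_vec(id, "A", date, list())
    v$af_new_onset <- onset
    v$af_prior_history <- prior
    v
  }
  # no onset anywhere -> absent
  r <- resolve_debut(list(mk("A-R1", "2019-01-01", FALSE, FALSE)))
  expect_true(is.na(r$debut_date))
  # prior history at day 0, onset claim at day 30 -> no debut
  r <- resolve_debut(list(mk("A-R1", "2019-01-01", FALSE, TRUE),
                          mk("A-R2", "2019-01-31", TRUE, FALSE)))
  expect_true(is.na(r$debut_date))
  # single clean onset
  r <- resolve_debut(list(mk("A-R1", "2019-01-01", TRUE, FALSE)))
  expect_equal(r$debut_date, as.Date("2019-01-01"))
  expect_equal(r$af_onset_report_id, "A-R1")
  # later AF mentions become recurrence candidates
  r <- resolve_debut(list(mk("A-R1", "2019-01-01", TRUE, FALSE),
                          mk("A-R2", "2019-05-01", FALSE, TRUE)))
  expect_equal(r$recurrence_report_ids, "A-R2")
})

test_that("missingness arithmetic and input contracts", {
  ext <- data.frame(patient_id = sprintf("P%d", 1:10),
                    creatinine = c(rep(NA, 2), rnorm(8)))
  cod <- data.frame(patient_id = sprintf("P%d", 1:10),
                    creatinine = c(rep(NA, 4), rnorm(6)))
  m <- missingness(ext, cod)
  expect_equal(m$reduction[m$variable == "creatinine"], 0.5)
  # identical missingness -> reduction 0
  m0 <- missingness(cod, cod)
  expect_equal(m0$reduction[m0$variable == "creatinine"], 0)
  # disjoint id sets are an input error
  ext2 <- ext
  ext2$patient_id <- sprintf("Q%d", 1:10)
  expect_error(missingness(ext2, cod), "input error")
})
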