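test_that("a minimal trio is read, sorted and validated", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam", "C,A,B", "A,,", "B,,"), tmp)
  ped <- suppressMessages(read_pedigree(tmp))
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_gt(match("C", ped$id), max(match(c("A", "B"), ped$id)))
  expect_equal(ped$sex[ped$id == "A"], "male")
  expect_equal(ped$sex[ped$id == "B"], "female")
})

test_that("structural errors are rejected", {
  expect_error(
    as_pedigree(data.frame(id = c("A", "C"), sire = c("C", "A"),
                           dam = c(NA, NA))),
    "cycle"
  )
  expect_error(
    as_pedigree(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
    "duplicate"
  )
  expect_error(
    as_pedigree(data.frame(id = c("A", "B", "C"), sire = c(NA, "A", NA),
                           dam = c(NA, NA, "A"))),
    "both sire and dam"
  )
  expect_error(
    as_pedigree(data.frame(id = "A", sire = "A", dam = NA)),
    "cycle"
  )
})

test_that("unknown-parent codes are all accepted", {
  ped <- as_pedigree(data.frame(id = c("A", "B", "C", "D"),
                                sire = c("", "0", "NA", NA),
                                dam = c(NA, "", "0", "NA")))
  expect_true(all(is.na(ped$sire)))
  expect_true(all(is.na(ped$dam)))
})

test_that("a large pedigree round-trips through write/read unchanged", {
  cfg <- sim_config(n_founders = 300, first_year = 1990, n_years = 7,
                    offspring_per_year = 100, true_genetic_trend = 0)
  ped <- suppressMessages(simulate_pedigree(cfg, seed = 11))$ped
  expect_equal(nrow(ped), 1000)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, tmp)
  ped2 <- suppressMessages(read_pedigree(tmp))
  expect_equal(as.data.frame(ped2), as.data.frame(ped))
})

test_that("trimming keeps phenotyped animals plus ancestors only", {
  trio <- trio_pedigree()
  expect_equal(sort(trim_pedigree(trio, "C")$id), c("A", "B", "C"))

  four <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D"), sire = c(NA, NA, "A", "A"),
    dam = c(NA, NA, "B", "B")
  ))
  tr <- trim_pedigree(four, "C")
  expect_equal(sort(tr$id), c("A", "B", "C"))

  expect_error(trim_pedigree(trio, c("C", "ZZZ")), "absent")
})

test_that("trimming matches the ancestor-closure oracle and is idempotent", {
  ped <- random_pedigree(500, seed = 5)
  set.seed(9)
  phen <- sample(ped$id, 100)
  tr <- trim_pedigree(ped, phen)
  expect_equal(sort(tr$id), ancestor_closure_oracle(ped, phen))
  tr2 <- trim_pedigree(tr, phen)
  expect_equal(as.data.frame(tr2), as.data.frame(tr))
})

test_that("relationship matrix reproduces textbook identities", {
  two <- as_pedigree(data.frame(id = c("A", "B"), sire = NA, dam = NA))
  expect_equal(relationship_matrix(two), diag(2), ignore_attr = TRUE)

  A <- relationship_matrix(fullsib_mating_pedigree())
  expect_equal(A["O", "O"], 1.25)
  expect_equal(A["S1", "S2"], 0.5)
  expect_equal(unname(inbreeding(fullsib_mating_pedigree())["O"]), 0.25)
})

test_that("tabular A equals twice the recursive kinship oracle", {
  for (seed in 1:3) {
    ped <- random_pedigree(50, seed = seed)
    A <- relationship_matrix(ped)
    K <- kinship_oracle(ped)
    expect_lt(max(abs(A - 2 * K)), 1e-12)
  }
  # and inbreeding agrees with the oracle diagonal
  ped <- random_pedigree(50, seed = 4)
  expect_lt(max(abs(inbreeding(ped) - (2 * diag(kinship_oracle(ped)) - 1))),
            1e-12)
})

test_that("relationship matrices are symmetric PSD with sane entries", {
  for (seed in 1:3) {
    ped <- random_pedigree(150, seed = seed + 10)
    A <- relationship_matrix(ped)
    expect_identical(A, t(A))
    expect_true(all(diag(A) >= 1 & diag(A) <= 2))
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    # non-inbred animals have diagonal exactly 1
    F <- inbreeding(ped)
    expect_true(all(diag(A)[F == 0] == 1))
  }
})

test_that("sparse A-inverse matches the dense inverse and log-determinant", {
  ped <- random_pedigree(80, seed = 7)
  A <- relationship_matrix(ped)
  Ai <- ainverse(ped)
  expect_lt(max(abs(as.matrix(Ai) - solve(A))), 1e-8)
  expect_equal(attr(Ai, "logdet"),
               as.numeric(determinant(A, logarithm = TRUE)$modulus))
})

test_that("pedigree summaries count structure correctly", {
  one <- as_pedigree(data.frame(id = "A", sire = NA, dam = NA))
  s1 <- summarize_pedigree(one)
  expect_equal(s1$max_depth, 1L)
  expect_equal(s1$max_paternal_halfsib, 0L)

  s2 <- summarize_pedigree(trio_pedigree())
  expect_equal(s2$max_depth, 2L)
  expect_equal(s2$max_paternal_halfsib, 1L)

  # one sire with exactly 40 offspring
  ped <- as_pedigree(data.frame(
    id = c("S", paste0("D", 1:40), paste0("K", 1:40)),
    sire = c(NA, rep(NA, 40), rep("S", 40)),
    dam = c(NA, rep(NA, 40), paste0("D", 1:40))
  ))
  s3 <- summarize_pedigree(ped)
  expect_equal(s3$max_paternal_halfsib, 40L)
  expect_equal(s3$max_maternal_halfsib, 1L)

  # sires with offspring that have records
  recs <- make_records(horse = "C", speed = 16)
  expect_equal(summarize_pedigree(trio_pedigree(),
                                  recs)$n_sires_with_offspring_records, 1L)
})

test_that("an unsorted pedigree is sorted internally with a message", {
  df <- data.frame(id = c("C", "A", "B"), sire = c("A", NA, NA),
                   dam = c("B", NA, NA))
  ped <- as_pedigree(df, sort = FALSE)
  expect_message(A <- relationship_matrix(ped), "sorting")
  expect_equal(A["C", "A"], 0.5)
})
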