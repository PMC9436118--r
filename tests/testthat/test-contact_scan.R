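test_that("scan region trims only low-confidence termini", {
  m6 <- point_model(cbind(seq_len(6) * 4, 0, 0))
  # uniform: equality with the mean is confident, nothing trimmed
  expect_equal(unname(scan_region(with_plddt(m6, rep(80, 6)))), c(1, 6))
  # mean 70: both 50-termini trimmed
  expect_equal(unname(scan_region(with_plddt(m6, c(50, 50, 90, 90, 90, 50)))),
               c(3, 5))
  # internal dip below the mean is NOT trimmed
  m4 <- point_model(cbind(seq_len(4) * 4, 0, 0))
  expect_equal(unname(scan_region(with_plddt(m4, c(90, 50, 90, 90)))),
               c(1, 4))
  expect_error(scan_region(m4), "pLDDT")
})

test_that("window tiling covers the region with a re-anchored last window", {
  cfg <- scan_config(window_length = 11)
  expect_equal(enumerate_windows(c(1, 33), cfg),
               data.frame(start = c(1, 12, 23), end = c(11, 22, 33)))
  expect_equal(enumerate_windows(c(1, 30), cfg),
               data.frame(start = c(1, 12, 20), end = c(11, 22, 30)))
  expect_equal(enumerate_windows(c(1, 8), cfg),
               data.frame(start = 1, end = 8))
  # property: windows exactly cover arbitrary regions
  set.seed(42)
  for (rep_ in 1:20) {
    region <- sort(sample(200, 2))
    w <- sample(3:15, 1)
    wins <- enumerate_windows(region, scan_config(window_length = w))
    covered <- sort(unique(unlist(Map(seq, wins$start, wins$end))))
    expect_identical(covered, region[1]:region[2])
  }
})

test_that("contacts above the cutoff and inside the sequence exclusion are omitted", {
  # residues 1..11 along x at 10 A spacing (window, far apart), partners:
  # res 14 at 3 A from res 11 (excluded: |14-11| <= 4), res 16 at 3.5 A
  # (kept), res 17 at 4.5 A (above cutoff), res 20 far away
  coords <- rbind(cbind(seq_len(11) * 10, 0, 0),
                  matrix(c(200, 200, 0,   # 12
                           210, 200, 0,   # 13
                           110, 3, 0,     # 14 near res 11, excluded
                           220, 200, 0,   # 15
                           110, 0, 3.5,   # 16 contact with res 11
                           110, 4.5, 0,   # 17 just above cutoff
                           230, 200, 0,   # 18
                           240, 200, 0,   # 19
                           250, 200, 0),  # 20
                         ncol = 3, byrow = TRUE))
  m <- point_model(coords)
  ms <- window_contacts(m, c(1, 11), scan_config())
  expect_identical(ms$positions, c(11L, 16L))
  pairs <- attr(ms, "pairs")
  expect_identical(nrow(pairs), 1L)
  expect_identical(c(pairs$i, pairs$j), c(11L, 16L))
  # 4.5 A pair appears once the cutoff is widened
  wide <- window_contacts(m, c(1, 11), scan_config(contact_cutoff = 4.6))
  expect_true(17L %in% wide$positions)
  # mutate side switch
  expect_identical(
    window_contacts(m, c(1, 11), scan_config(mutate = "window"))$positions,
    11L)
  expect_identical(
    window_contacts(m, c(1, 11), scan_config(mutate = "partners"))$positions,
    16L)
  expect_error(window_contacts(m, c(15, 26)), "out of range")
})

test_that("window contacts equal the brute-force all-atom-pair oracle", {
  set.seed(7)
  for (rep_ in 1:5) {
    angle <- runif(1, 130, 160)
    m <- hinge_model(toy_spec(noise_sd = 0.15), angle)
    region <- scan_region(m)
    wins <- enumerate_windows(region, scan_config())
    k <- sample(nrow(wins), 1)
    win <- c(wins$start[k], wins$end[k])
    got <- window_contacts(m, win, scan_config())$positions
    expect_identical(got, brute_contact_set(m, win))
  }
})

test_that("contact sets are rigid-motion invariant and monotone in cutoff", {
  m <- toy_closed()
  win <- c(15, 25)
  base <- window_contacts(m, win)$positions
  for (s in 1:3) {
    mo <- random_rigid_motion(s)
    mt <- transform_model(m, mo$rotation, mo$translation)
    expect_identical(window_contacts(mt, win)$positions, base)
  }
  prev <- integer(0)
  for (cut in c(2, 3, 4, 5, 6)) {
    cur <- window_contacts(m, win, scan_config(contact_cutoff = cut))$positions
    expect_true(all(prev %in% cur))  # shrinking cutoff never adds residues
    prev <- cur
  }
})

test_that("targeted mode finds the inter-group interface or takes a list", {
  # two parallel helices 10 A apart: no 4-A contact
  spec <- toy_spec()
  far <- hinge_model(spec, 90)
  expect_length(targeted_set(far, 1:25, 31:55, cutoff = 4)$positions, 0)
  # closed toy: equality with the brute-force inter-group enumeration
  m <- toy_closed()
  got <- targeted_set(m, 1:25, 31:55, cutoff = 4)$positions
  at <- m$atoms
  exp_pos <- integer(0)
  for (i in 1:25) for (j in 31:55) {
    ai <- as.matrix(at[at$res_index == i, c("x", "y", "z")])
    aj <- as.matrix(at[at$res_index == j, c("x", "y", "z")])
    d2 <- outer(rowSums(ai^2), rowSums(aj^2), `+`) - 2 * ai %*% t(aj)
    if (min(d2) <= 16) exp_pos <- c(exp_pos, i, j)
  }
  expect_identical(got, sort(unique(exp_pos)))
  expect_error(targeted_set(m, 1:10, 5:20), "overlap")
  # list mode is verbatim
  expect_identical(targeted_set(m, positions = c(9, 3, 3, 40))$positions,
                   c(3L, 9L, 40L))
})

test_that("scan_sets drops contactless windows and stays in range", {
  m <- toy_closed()
  sets <- scan_sets(m)
  expect_gt(length(sets), 2)
  for (s in sets) {
    expect_gt(length(s$positions), 0)
    expect_true(all(s$positions >= 1 & s$positions <= n_residues(m)))
  }
  ids <- vapply(sets, function(s) s$set_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  # open conformation: every window is contact-free, all flagged empty
  open_far <- hinge_model(toy_spec(), 90)
  sets2 <- scan_sets(open_far)
  expect_length(sets2, 0)
  expect_gt(nrow(attr(sets2, "empty_windows")), 0)
})

test_that("mutation sets round-trip through JSON", {
  m <- toy_closed()
  sets <- scan_sets(m)
  path <- withr::local_tempfile(fileext = ".json")
  write_mutation_sets(sets, path)
  back <- read_mutation_sets(path)
  expect_equal(lapply(back, function(s) s[c("set_id", "positions")]),
               lapply(sets, function(s) s[c("set_id", "positions")]))
})
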