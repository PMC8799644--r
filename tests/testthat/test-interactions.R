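# Geometric interaction criteria: boundary semantics, frequency tabulation
# and invariances.

test_that("every criterion is satisfied at its cutoff and fails just beyond", {
  cases <- list(
    list(kind = "hbond", args = list(distance = 2.5)),
    list(kind = "hbond", args = list(distance = 2.6), expect = 0),
    list(kind = "hbond", args = list(distance = 2.4, donor_angle = 120)),
    list(kind = "hbond", args = list(distance = 2.4, donor_angle = 119),
         expect = 0),
    list(kind = "hbond", args = list(distance = 2.4, acceptor_angle = 90)),
    list(kind = "hbond", args = list(distance = 2.4, acceptor_angle = 89),
         expect = 0),
    list(kind = "pication", args = list(distance = 4.5)),
    list(kind = "pication", args = list(distance = 4.6), expect = 0),
    list(kind = "saltbridge", args = list(distance = 4.0)),
    list(kind = "saltbridge", args = list(distance = 4.1), expect = 0),
    list(kind = "waterbridge", args = list(distance = 2.8)),
    list(kind = "waterbridge", args = list(distance = 2.9), expect = 0)
  )
  detectors <- list(hbond = detect_hbonds, pication = detect_pication,
                    saltbridge = detect_saltbridge,
                    waterbridge = detect_waterbridge)
  for (cs in cases) {
    fx <- do.call(gen_interaction_fixture, c(list(kind = cs$kind), cs$args))
    ev <- detectors[[cs$kind]](fx$structure)
    expect_equal(nrow(ev), cs$expect %||% 1,
                 info = paste(cs$kind, paste(names(cs$args), unlist(cs$args),
                                             collapse = " ")))
  }
})

test_that("pi-pi stacking distinguishes face-to-face and edge-to-face", {
  f2f <- gen_interaction_fixture("pipi", distance = 3.8, plane_angle = 0)
  ev <- detect_pipi(f2f$structure)
  expect_equal(ev$geometry, "face_to_face")
  e2f <- gen_interaction_fixture("pipi", distance = 5.0, plane_angle = 90)
  ev <- detect_pipi(e2f$structure)
  expect_equal(ev$geometry, "edge_to_face")
  far <- gen_interaction_fixture("pipi", distance = 6.0, plane_angle = 0)
  expect_equal(nrow(detect_pipi(far$structure)), 0)
  # face-to-face boundary: 4.4 A in, 4.5 A only edge-to-face window check
  expect_equal(nrow(detect_pipi(
    gen_interaction_fixture("pipi", distance = 4.4)$structure)), 1)
})

test_that("pi-cation detection region boundary sits at the cutoff on a grid scan", {
  # exhaustive grid oracle: scan charge distances in 0.05 A steps
  ds <- seq(4.0, 5.0, by = 0.05)
  fired <- vapply(ds, function(d)
    nrow(detect_pication(gen_interaction_fixture("pication",
                                                 distance = d)$structure)) > 0,
    logical(1))
  expect_true(all(fired[ds <= 4.5]))
  expect_false(any(fired[ds > 4.5]))
})

test_that("detection is invariant under rigid transforms of the whole frame", {
  for (kind in c("hbond", "pication", "pipi", "waterbridge", "saltbridge")) {
    fx <- gen_interaction_fixture(kind)
    det <- switch(kind, hbond = detect_hbonds, pication = detect_pication,
                  pipi = detect_pipi, waterbridge = detect_waterbridge,
                  saltbridge = detect_saltbridge)
    before <- det(fx$structure)
    after <- det(transform_structure(fx$structure))
    expect_equal(nrow(after), nrow(before), info = kind)
  }
})

test_that("hbond detector agrees with an exhaustive brute-force check", {
  # randomly scattered donor/acceptor triples; compare against a direct
  # enumeration of the geometric definition
  set.seed(21)
  for (rep in 1:5) {
    n <- 6
    a <- restime:::synthetic_atoms(3 * n)
    pos <- matrix(runif(9 * n, 0, 8), ncol = 3)
    a[, c("x", "y", "z")] <- pos
    don <- seq(1, 3 * n, by = 3); hyd <- don + 1; acc <- don + 2
    a$element[don] <- "N"; a$element[hyd] <- "H"; a$element[acc] <- "O"
    a$name <- paste0(a$element, seq_len(3 * n))
    a$resno <- rep(seq_len(n), each = 3)
    a$donor[don] <- TRUE; a$hydrogen[hyd] <- TRUE; a$hydrogen_of[hyd] <- don
    a$acceptor[acc] <- TRUE
    # place each H 1 A from its donor
    for (k in seq_len(n)) {
      v <- pos[hyd[k], ] - pos[don[k], ]
      a[hyd[k], c("x", "y", "z")] <- pos[don[k], ] + v / sqrt(sum(v^2))
    }
    s <- restime:::new_structure(a)
    ev <- detect_hbonds(s)
    xyz <- restime:::coords(s)
    brute <- 0
    for (h in hyd) for (ac in acc) {
      if (ac == a$hydrogen_of[h]) next
      d <- sqrt(sum((xyz[h, ] - xyz[ac, ])^2))
      if (d > 2.5) next
      ang <- restime:::angle_deg(xyz[a$hydrogen_of[h], ], xyz[h, ], xyz[ac, ])
      if (ang < 120) next
      brute <- brute + 1   # isolated acceptors have no neighbour constraint
    }
    expect_equal(nrow(ev), brute)
  }
})

test_that("frequencies follow the strict >15 percent filter", {
  mk_events <- function(n_obs) data.frame(
    frame = seq_len(n_obs), kind = "hbond", partner_a = "a", partner_b = "b",
    bridging_water = NA_character_)
  t15 <- tabulate_frequencies(mk_events(15), 100, min_frequency = 0.15)
  expect_equal(nrow(t15), 0)
  t16 <- tabulate_frequencies(mk_events(16), 100, min_frequency = 0.15)
  expect_equal(t16$frequency, 0.16)
  expect_equal(nrow(tabulate_frequencies(restime:::empty_events(), 10)), 0)
  expect_error(tabulate_frequencies(mk_events(1), 0), "n_frames")
})

test_that("frequencies count frames, not events, and ignore frame order", {
  # two waters bridging the same pair in one frame collapse to one pair-frame
  ev <- data.frame(frame = c(1, 1, 2), kind = "waterbridge",
                   partner_a = "LIG1:O1", partner_b = "GLY2:N",
                   bridging_water = c("HOH7", "HOH9", "HOH7"))
  tab <- tabulate_frequencies(ev, 4)
  expect_equal(tab$n_obs, 2)
  expect_equal(tab$frequency, 0.5)
  shuf <- ev[c(3, 1, 2), ]
  expect_equal(tabulate_frequencies(shuf, 4), tab)
})

test_that("planted on-fractions are recovered from trajectories", {
  fx <- gen_interaction_fixture("hbond", n_frames = 100, on_fraction = 0.95,
                                seed = 5)
  tab <- tabulate_frequencies(detect_interactions(fx$trajectory,
                                                  kinds = "hbond"), 100)
  expect_equal(tab$frequency, 0.95)
  # alternating salt-bridge partners 88:12
  fx1 <- gen_interaction_fixture("saltbridge", n_frames = 100,
                                 on_fraction = 0.88, seed = 6)
  tab <- tabulate_frequencies(detect_interactions(fx1$trajectory,
                                                  kinds = "saltbridge"), 100)
  expect_equal(tab$frequency, 0.88)
})

test_that("criteria constructor validates bounds", {
  expect_error(interaction_criteria(hbond_distance = -1), "> 0")
  expect_error(interaction_criteria(hbond_donor_angle_min = 200), "0, 180")
})
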