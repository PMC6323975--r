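# Reaction-center identification and stereo augmentation.

test_that("bond, charge and existence changes define the center", {
  # charge-only change
  r <- parse_mapped_reaction("[CH3:1][OH:2]>>[CH3:1][O-:2]")
  expect_equal(identify_reaction_center(r)$reacting_maps, 2L)

  # identity reaction: empty center
  r2 <- parse_mapped_reaction("[OH2:1]>>[OH2:1]")
  expect_length(identify_reaction_center(r2)$reacting_maps, 0L)

  # transamination: keto C/O on one substrate, amine C/N on the other --
  # exactly two reacting atoms per substrate
  tx1 <- test_corpus()$reactions[[1]]
  ctr <- identify_reaction_center(tx1)
  expect_length(ctr$reacting_maps, 4L)
  for (side in tx1$substrates) {
    expect_equal(sum(side$atoms$map %in% ctr$reacting_maps), 2L)
  }
  # the reacting atoms are the amine N + alpha C and the keto C + O
  syms <- unlist(lapply(tx1$substrates, function(m)
    m$atoms$symbol[m$atoms$map %in% ctr$reacting_maps]))
  expect_setequal(syms, c("N", "C", "C", "O"))
})

test_that("center equals the brute-force per-atom environment diff", {
  for (rxn in test_corpus()$reactions) {
    if (!is.null(rxn$defect)) next
    expect_equal(identify_reaction_center(rxn)$reacting_maps,
                 brute_force_center(rxn), info = rxn$reaction_id)
  }
})

test_that("center is symmetric under reaction reversal", {
  for (rxn in test_corpus()$reactions) {
    if (!is.null(rxn$defect)) next
    fwd <- identify_reaction_center(rxn)
    rev <- identify_reaction_center(ruleforge:::reverse_reaction(rxn))
    expect_equal(fwd$reacting_maps, rev$reacting_maps, info = rxn$reaction_id)
  }
})

test_that("stereo augmentation adds R/S and E/Z changing atoms, never removes", {
  corpus <- test_corpus()
  byid <- function(id) corpus$reactions[[which(corpus$expected$id == id)]]

  # racemization: empty plain center, stereo center = the alpha carbon
  rc <- byid("RC1")
  plain <- identify_reaction_center(rc)
  expect_length(plain$reacting_maps, 0L)
  aug <- augment_stereo(rc, plain)
  expect_true(aug$is_stereo_augmented)
  expect_equal(aug$reacting_maps, 2L)   # the chiral alpha carbon
  expect_equal(aug$stereo_added_maps, 2L)
  alpha <- rc$substrates[[1]]$atoms
  expect_equal(alpha$symbol[alpha$map == 2L], "C")

  # cis-trans switch: both sp2 carbons of the flipping double bond
  ct <- byid("CT1")
  aug2 <- augment_stereo(ct, identify_reaction_center(ct))
  expect_setequal(aug2$reacting_maps, c(4L, 5L))

  # no stereo anywhere: augmentation is the identity on the map set
  cn <- byid("CN1")
  plain_cn <- identify_reaction_center(cn)
  aug3 <- augment_stereo(cn, plain_cn)
  expect_equal(aug3$reacting_maps, plain_cn$reacting_maps)
  expect_length(aug3$stereo_added_maps, 0L)

  # augmentation output always contains the input center
  for (rxn in corpus$reactions) {
    if (!is.null(rxn$defect)) next
    ctr <- identify_reaction_center(rxn)
    expect_true(all(ctr$reacting_maps %in%
                      augment_stereo(rxn, ctr)$reacting_maps),
                info = rxn$reaction_id)
  }
})

test_that("stereo creation against an undefined descriptor is detected", {
  # hydration creates a stereocenter on an sp2 carbon; it is already in the
  # bonding center, but a pure descriptor creation must be picked up too:
  r <- parse_mapped_reaction(paste0(
    "[NH2:1][CH:2]([CH3:3])[C:4](=[O:5])[OH:6]>>",
    "[NH2:1][C@@H:2]([CH3:3])[C:4](=[O:5])[OH:6]"), "CREATE")
  plain <- identify_reaction_center(r)
  expect_length(plain$reacting_maps, 0L)
  expect_equal(augment_stereo(r, plain)$reacting_maps, 2L)
})
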