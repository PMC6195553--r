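test_that("star polymers have the cross architecture", {
  s <- build_star(c(3, 4))
  expect_equal(nrow(s$beads), 9L)        # 1 core + 4 arms x 2 monomers
  expect_equal(nrow(s$bonds), 8L)        # tree: beads - 1
  expect_equal(length(s$end_ids), 4L)
  # ends sit at twice the arm spacing from the center
  ends <- s$beads[s$beads$role == "end", ]
  r <- sqrt((ends$ux - 3)^2 + (ends$uy - 4)^2)
  expect_equal(r, rep(2, 4))
  s2 <- build_star(c(0, 0), spacing = 0.7)
  ends2 <- s2$beads[s2$beads$role == "end", ]
  expect_equal(sqrt(ends2$ux^2 + ends2$uy^2), rep(1.4, 4))

  # 3D variant: 6 arms along the axes
  s3 <- build_star(c(0, 0, 0), d = 3)
  expect_equal(nrow(s3$beads), 13L)
  expect_equal(nrow(s3$bonds), 12L)
  expect_equal(length(s3$end_ids), 6L)
})

test_that("lattice gels assemble with overlapping facing ends", {
  gel <- tiny_gel(saturated = FALSE)
  expect_equal(nrow(gel$beads), 36L)     # 4 stars x 9 monomers
  expect_equal(nrow(gel$sites), 16L)
  # construction is deterministic
  gel2 <- build_gel(2L, seed = 99L)
  expect_identical(gel$beads, gel2$beads)
  # every end has an overlapping complementary end (gap < 0)
  ends <- gel$sites$bead
  gaps <- geldiff:::pair_gaps(gel, ends)
  gaps <- gaps[gaps$i != gaps$j, ]
  min_gap_per_end <- tapply(gaps$gap, gaps$i, min)
  expect_length(min_gap_per_end, length(ends))
  expect_true(all(min_gap_per_end < 0))
  # unphysical spacing is refused
  expect_error(build_gel(2L, overlap = 0), "overlap")
})

test_that("saturation pairs all facing ends and is idempotent", {
  gel <- tiny_gel(saturated = FALSE)
  gel <- saturate_crosslinks(gel)
  # 2x2 periodic lattice: 2 horizontal + 2 vertical facing pairs per row/col
  expect_equal(count_bonds(gel), 8L)
  expect_equal(sum(gel$sites$state == "free"), 0L)
  expect_equal(gel$meta$free_sites, 0L)
  again <- saturate_crosslinks(gel)
  expect_identical(gel$sites, again$sites)
  audit_gel(gel)

  # two overlapping free ends -> exactly one crosslink
  g <- frozen_triplet(particle = FALSE)
  g <- saturate_crosslinks(g)
  expect_equal(count_bonds(g), 1L)
  expect_equal(g$sites$partner, c(2L, 1L))
})

test_that("shell trimming deletes whole stars within the radial band", {
  gel <- build_gel(8L) |> saturate_crosslinks()
  L <- gel$box[1]
  shell <- trim_to_shell(gel, 0.25 * L, 0.45 * L)
  # every surviving star center lies inside the band
  cores <- shell$beads[shell$beads$role == "core", ]
  r <- sqrt((cores$x - L / 2)^2 + (cores$y - L / 2)^2)
  expect_true(all(r >= 0.25 * L - 1e-9 & r <= 0.45 * L + 1e-9))
  # stars are removed whole: bead count is a multiple of 9
  expect_equal(nrow(shell$beads) %% 9L, 0L)
  # no dangling references
  audit_gel(shell)
  expect_true(all(shell$bonds$i %in% shell$beads$id))
  expect_true(all(stats::na.omit(shell$sites$partner) %in% shell$beads$id))

  # r_inner = 0 keeps the full disk including the center star
  disk <- trim_to_shell(build_gel(4L), 0, 0.45 * build_gel(4L)$box[1])
  expect_gt(nrow(disk$beads), 0)
  cores_d <- disk$beads[disk$beads$role == "core", ]
  rd <- sqrt((cores_d$x - disk$box[1] / 2)^2 + (cores_d$y - disk$box[2] / 2)^2)
  expect_lt(min(rd), 0.25 * disk$box[1])
  # r_outer beyond the box circumradius only carves the cavity
  gel4 <- build_gel(4L)
  carved <- trim_to_shell(gel4, 6, 1.1 * gel4$box[1])
  expect_equal(
    sum(sqrt((carved$beads$x - gel4$box[1] / 2)^2 +
               (carved$beads$y - gel4$box[2] / 2)^2)[carved$beads$role == "core"] < 6),
    0L)
  # a shell too thin to hold any star errors
  expect_error(trim_to_shell(gel4, 0.1, 0.2), "shell")
})

test_that("particle insertion respects region, overlaps and determinism", {
  gel <- tiny_gel()
  g1 <- place_particles(gel, n_binding = 1L, seed = 5)
  expect_equal(sum(g1$beads$role == "particle"), 1L)
  expect_true(g1$beads$binding[g1$beads$role == "particle"])
  g1b <- place_particles(gel, n_binding = 1L, seed = 5)
  expect_identical(g1$beads, g1b$beads)

  # 10 + 10 inside a disk region: all inside, none overlapping
  big <- build_gel(6L) |> saturate_crosslinks()
  shell <- trim_to_shell(big) |> saturate_crosslinks(deactivate_remaining = TRUE)
  ri <- 0.25 * big$box[1]
  g2 <- place_particles(shell, 3L, 3L,
                        region = region_disk(ri - 1.2, big$box / 2),
                        seed = 8)
  parts <- g2$beads[g2$beads$role == "particle", ]
  expect_equal(nrow(parts), 6L)
  expect_equal(sum(parts$binding), 3L)
  r <- sqrt((parts$x - big$box[1] / 2)^2 + (parts$y - big$box[2] / 2)^2)
  expect_true(all(r < ri))
  gaps <- geldiff:::pair_gaps(g2, parts$id, g2$beads$id)
  gaps <- gaps[gaps$i != gaps$j, ]
  expect_true(all(gaps$gap > -1e-9))

  # a region with no free volume errors out
  expect_error(
    place_particles(gel, 1L, 0L, region = function(p) FALSE, seed = 1,
                    max_attempts = 50L),
    "free volume")
})

test_that("dangling shell sites can be deactivated for saturation", {
  gel <- build_gel(6L) |> trim_to_shell()
  expect_warning(saturate_crosslinks(gel), "free binding site")
  g <- suppressWarnings(saturate_crosslinks(gel, deactivate_remaining = TRUE))
  expect_equal(sum(g$sites$state == "free" & g$sites$active), 0L)
  expect_gt(sum(!g$sites$active), 0L)
  audit_gel(g)
})
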