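test_that("common grid covers every atom with the requested margin", {
  m <- make_mol("one", c(0, 0, 0))
  g <- build_common_grid(list(m), margin = 6, spacing = 0.5)
  expect_true(all(g$dims >= 25))  # at least [-6, 6] at 0.5 A
  top <- g$origin + (g$dims - 1) * g$spacing
  expect_true(all(g$origin <= -6 + 1e-9))
  expect_true(all(top >= 6 - 1e-9))

  # monotonicity: the joint grid contains each single-molecule grid
  m2 <- make_mol("two", c(8, -3, 2))
  g1 <- build_common_grid(list(m))
  g2 <- build_common_grid(list(m2))
  gj <- build_common_grid(list(m, m2))
  for (gi in list(g1, g2)) {
    expect_true(all(gj$origin <= gi$origin + 1e-9))
    expect_true(all(gj$origin + (gj$dims - 1) * gj$spacing >=
                      gi$origin + (gi$dims - 1) * gi$spacing - 1e-9))
  }

  g0 <- build_common_grid(list(m), margin = 0, spacing = 0.5)
  expect_true(all(g0$dims == 2))  # tight box snapped outward
  expect_error(build_common_grid(list()), "no atoms")
})

test_that("shape field matches the brute-force sphere oracle", {
  mol <- make_mol("s", c(0, 0, 0), radius = 2.0)
  g <- grid_spec(c(-3, -3, -3), 0.5, c(13, 13, 13))
  f <- shape_field(mol, g)
  pts <- as.matrix(expand.grid(
    x = g$origin[1] + g$spacing * (0:(g$dims[1] - 1)),
    y = g$origin[2] + g$spacing * (0:(g$dims[2] - 1)),
    z = g$origin[3] + g$spacing * (0:(g$dims[3] - 1))))
  # oracle: direct distance test, same storage order (x fastest)
  oracle <- as.numeric(sqrt(rowSums(pts^2)) <= 2.0 + 1e-9)
  expect_equal(f$values, oracle)
  expect_gt(sum(f$values), 0)
})

test_that("shape field of a two-atom molecule is the union of spheres", {
  a <- make_mol("a", c(0, 0, 0), radius = 1.5)
  b <- make_mol("b", c(4, 0, 0), radius = 1.5)
  ab <- make_mol("ab", rbind(c(0, 0, 0), c(4, 0, 0)), radius = 1.5)
  g <- build_common_grid(list(ab), margin = 3, spacing = 0.5)
  fa <- shape_field(a, g)$values
  fb <- shape_field(b, g)$values
  fab <- shape_field(ab, g)$values
  expect_equal(fab, pmax(fa, fb))
  empty <- make_mol("e", matrix(numeric(0), ncol = 3))
  expect_equal(sum(shape_field(empty, g)$values), 0)
})

test_that("electrostatic field reproduces hand Coulomb values", {
  # single +1 charge at origin; probes on the x axis
  mol <- make_mol("q", c(0, 0, 0), radius = 1.5, charge = 1)
  g <- grid_spec(c(0, 0, 0), 1, c(11, 2, 2))
  f_unc <- electrostatic_field(mol, g, clamp = NA)
  at <- function(ix) f_unc$values[ix + 1]  # iy = iz = 0 row, x fastest
  expect_equal(at(4), 332.0716 / (4 * 16))   # d = 4 A -> 5.189
  expect_equal(at(10), 332.0716 / (4 * 100)) # d = 10 A -> 0.830
  expect_equal(at(0), 0)                     # inside vdW sphere
  expect_equal(at(1), 0)                     # 1.0 < 1.5 still inside

  f_cl <- electrostatic_field(mol, g, clamp = 5)
  expect_equal(f_cl$values[5], 5)            # 5.189 truncated
  expect_true(all(abs(f_cl$values) <= 5))

  neutral <- make_mol("n", c(0, 0, 0), radius = 1.5, charge = 0)
  expect_equal(sum(abs(electrostatic_field(neutral, g)$values)), 0)
})

test_that("electrostatic field is linear in charges before clamping", {
  g <- grid_spec(c(-4, -4, -4), 1, c(9, 9, 9))
  xyz <- rbind(c(0, 0, 0), c(1.5, 0.5, -0.5))
  m1 <- make_mol("m1", xyz, radius = 1.2, charge = c(0.3, -0.2))
  m2 <- make_mol("m2", xyz, radius = 1.2, charge = c(-0.1, 0.5))
  m12 <- make_mol("m12", xyz, radius = 1.2, charge = c(0.2, 0.3))
  f <- function(m) electrostatic_field(m, g, clamp = NA)$values
  expect_equal(f(m12), f(m1) + f(m2), tolerance = 1e-9)
})

test_that("doubling the margin never changes values at shared points", {
  mol <- make_mol("m", rbind(c(0.3, 0.1, -0.2), c(2.1, 0.7, 0.4)),
                  radius = 1.6, charge = c(0.4, -0.4))
  g1 <- build_common_grid(list(mol), margin = 3, spacing = 0.5)
  g2 <- build_common_grid(list(mol), margin = 6, spacing = 0.5)
  for (maker in list(shape_field,
                     function(m, g) electrostatic_field(m, g, clamp = 5))) {
    f1 <- maker(mol, g1)
    f2 <- maker(mol, g2)
    # locate g1's block inside g2 (origins share the spacing lattice)
    off <- round((g1$origin - g2$origin) / g1$spacing)
    a1 <- array(f1$values, g1$dims)
    a2 <- array(f2$values, g2$dims)
    sub <- a2[off[1] + seq_len(g1$dims[1]),
              off[2] + seq_len(g1$dims[2]),
              off[3] + seq_len(g1$dims[3])]
    expect_equal(as.numeric(sub), as.numeric(a1))
  }
})

test_that("field_stats reports the pooled in-range fraction", {
  g <- tiny_grid(2)  # 8 points
  z <- make_field(rep(0, 8), g, "electrostatic")
  expect_equal(field_stats(list(z))$fraction_in_range, 1.0)
  v <- make_field(c(6, rep(1, 7)), g, "electrostatic")
  # pooled over both fields: 15 of 16 within +-5
  st <- field_stats(list(z, v), bound = 5)
  expect_equal(st$fraction_in_range, 15 / 16)
  expect_equal(st$max, 6)
  st2 <- field_stats(make_field(c(rep(0, 9), 7) [1:8], g, "electrostatic"))
  expect_true(st2$fraction_in_range <= 1)
})

test_that("field export formats round-trip through their own readers", {
  mol <- make_mol("m", c(0, 0, 0), radius = 1.2, charge = 0.5)
  g <- grid_spec(c(-2, -2, -2), 1, c(5, 5, 5))
  f <- electrostatic_field(mol, g)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), grid_size(g))
  expect_equal(back$value, f$values)
  # CSV order contract: x fastest
  expect_equal(back$ix[1:6], c(0:4, 0))

  dx <- withr::local_tempfile(fileext = ".dx")
  write_field_dx(f, dx)
  lines <- readLines(dx)
  expect_match(lines[1], "counts 5 5 5")
  nums <- as.numeric(unlist(strsplit(paste(lines[8:49], collapse = " "), " +")))
  arr <- aperm(array(nums, rev(g$dims)), c(3, 2, 1))  # undo z-fastest
  expect_equal(as.numeric(arr), f$values, tolerance = 1e-5)
})
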