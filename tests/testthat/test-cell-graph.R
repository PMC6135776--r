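test_that("pair indexing enumerates the 10 unordered type pairs", {
  expect_identical(pair_index("M", "M"), 1L)
  expect_identical(pair_index("M", "I"), pair_index("I", "M"))
  # bijection over unordered pairs with repetition
  pairs <- expand.grid(a = cell_types(), b = cell_types(),
                       stringsAsFactors = FALSE)
  idx <- pair_index(pairs$a, pairs$b)
  expect_setequal(idx, 1:10)
  expect_length(pair_names(), 10L)
  expect_identical(pair_names()[1L], "MM")
  expect_error(pair_index("M", "X"), "unknown cell type")
})

test_that("tiling assigns each cell to exactly one half-open tile", {
  cells <- data.frame(x_um = c(0, 200, 50, 150, 250),
                      y_um = c(0, 0, 50, 50, 50),
                      cell_type = "M")
  tiles <- tile_cells(cells)
  key <- vapply(tiles, function(t) paste(t$row, t$col), "")
  expect_setequal(key, c("0 0", "0 1"))
  n <- vapply(tiles, function(t) nrow(t$cells), 0L)
  # (0,0) and the two x < 200 cells on the left; x = 200 and 250 on the right
  expect_equal(sort(n), c(2L, 3L))
  expect_equal(sum(n), nrow(cells))

  # half-open boundary: x = 200 belongs to column 1
  one <- tile_cells(data.frame(x_um = 200, y_um = 0, cell_type = "M"))
  expect_equal(one[[1L]]$col, 1)
  expect_equal(one[[1L]]$row, 0)

  expect_error(tile_cells(data.frame(x_um = -1, y_um = 0, cell_type = "M")),
               "negative coordinates")
  expect_identical(tile_cells(data.frame(x_um = numeric(0),
                                         y_um = numeric(0),
                                         cell_type = character(0))),
                   list())
})

test_that("random cells always land in exactly one covering tile", {
  set.seed(41)
  for (rep in 1:5) {
    cells <- data.frame(x_um = runif(200, 0, 1000),
                        y_um = runif(200, 0, 1000), cell_type = "I")
    tiles <- tile_cells(cells, tile_size_um = 150)
    expect_equal(sum(vapply(tiles, function(t) nrow(t$cells), 0L)), 200L)
    for (t in tiles) {
      expect_true(all(t$cells$x_um >= t$bounds["xmin"] &
                        t$cells$x_um < t$bounds["xmax"]))
      expect_true(all(t$cells$y_um >= t$bounds["ymin"] &
                        t$cells$y_um < t$bounds["ymax"]))
    }
  }
})

test_that("Delaunay network handles canonical and degenerate cases", {
  tri <- delaunay_network(data.frame(x_um = c(0, 10, 0), y_um = c(0, 0, 10),
                                     cell_type = "M"))
  expect_equal(nrow(tri$edges), 3L)

  two <- delaunay_network(data.frame(x_um = c(0, 5), y_um = c(0, 0),
                                     cell_type = c("M", "I")))
  expect_equal(two$edges, matrix(1:2, ncol = 2))

  one <- delaunay_network(data.frame(x_um = 0, y_um = 0, cell_type = "M"))
  expect_equal(nrow(one$edges), 0L)

  # collinear cells: consecutive-neighbor path, given out of order
  coll <- delaunay_network(data.frame(x_um = c(30, 0, 10, 20),
                                      y_um = c(30, 0, 10, 20),
                                      cell_type = "S"))
  expect_equal(edge_key(coll$edges), c("1-4", "2-3", "3-4"))

  # coincident coordinates merged with a warning, first type kept
  expect_warning(
    dup <- delaunay_network(data.frame(x_um = c(0, 0, 10), y_um = c(0, 0, 5),
                                       cell_type = c("M", "I", "S"))),
    "coincident")
  expect_equal(nrow(dup$vertices), 2L)
  expect_equal(dup$vertices$cell_type[1L], "M")
})

test_that("the 4-point worked example has the diagonal edge and its spectrum", {
  cells <- data.frame(x_um = c(0, 10, 0, 9), y_um = c(0, 0, 10, 9),
                      cell_type = c("M", "M", "I", "I"))
  net <- delaunay_network(cells)
  expect_equal(edge_key(net$edges), c("1-2", "1-3", "1-4", "2-4", "3-4"))
  # matches the independent empty-circumcircle oracle
  expect_equal(edge_key(net$edges),
               edge_key(oracle_delaunay_edges(cells$x_um, cells$y_um)))
  h <- connection_frequencies(net)$h
  expect_equal(unname(h[1:3]), c(0.2, 0.6, 0.2))
  expect_equal(sum(h), 1)
})

test_that("Delaunay edges equal the empty-circumcircle oracle on random sets", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(3:8, 1L)
    cells <- data.frame(x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
                        cell_type = sample(cell_types(), n, replace = TRUE))
    net <- delaunay_network(cells)
    expect_equal(edge_key(net$edges),
                 edge_key(oracle_delaunay_edges(cells$x_um, cells$y_um)),
                 info = paste("replicate", rep))
    # edge-count bound for a planar triangulation
    expect_lte(nrow(net$edges), 3 * n - 6)
  }
})

test_that("connection frequencies close to 1 and respect relabeling", {
  set.seed(7)
  cells <- data.frame(x_um = runif(40, 0, 100), y_um = runif(40, 0, 100),
                      cell_type = sample(cell_types(), 40, replace = TRUE))
  net <- delaunay_network(cells)
  h <- connection_frequencies(net)$h
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_true(all(h >= 0 & h <= 1))

  # permuting the type labels permutes h exactly through pair_index
  perm <- c(M = "S", I = "N", S = "M", N = "I")
  cells2 <- cells
  cells2$cell_type <- unname(perm[cells$cell_type])
  h2 <- connection_frequencies(delaunay_network(cells2))$h
  for (a in cell_types()) for (b in cell_types()) {
    expect_equal(unname(h[pair_index(a, b)]),
                 unname(h2[pair_index(perm[[a]], perm[[b]])]))
  }
})

test_that("single M triangle and single M-I edge give unit components", {
  tri <- connection_frequencies(delaunay_network(
    data.frame(x_um = c(0, 10, 0), y_um = c(0, 0, 10), cell_type = "M")))
  expect_equal(unname(tri$h[pair_index("M", "M")]), 1)
  mi <- connection_frequencies(delaunay_network(
    data.frame(x_um = c(0, 5), y_um = c(0, 0), cell_type = c("M", "I"))))
  expect_equal(unname(mi$h[pair_index("M", "I")]), 1)
  expect_equal(sum(mi$h), 1)
})

test_that("tile table is independent of cell processing order", {
  set.seed(13)
  cells <- data.frame(case_id = "c1",
                      x_um = runif(400, 0, 600), y_um = runif(400, 0, 600),
                      cell_type = sample(cell_types(), 400, replace = TRUE))
  tt1 <- tile_frequencies(cells)
  tt2 <- tile_frequencies(cells[sample(nrow(cells)), ])
  expect_equal(tt1, tt2)
  # no tile's vector depends on other tiles: recompute one tile alone
  t1 <- tt1[1L, ]
  sub <- cells[floor(cells$x_um / 200) == t1$col &
                 floor(cells$y_um / 200) == t1$row, ]
  tt_sub <- tile_frequencies(sub)
  expect_equal(as.numeric(tt_sub[1L, pair_names()]),
               as.numeric(t1[pair_names()]))
})

test_that("tiles below min_cells are flagged unphenotyped", {
  cells <- data.frame(case_id = "c1",
                      x_um = c(10, 20, 30, 40, 50, 250, 260),
                      y_um = c(10, 20, 30, 40, 50, 10, 20),
                      cell_type = "M")
  tt <- tile_frequencies(cells, min_cells = 5)
  expect_equal(tt$phenotyped, c(TRUE, FALSE))
  expect_equal(nrow(frequency_matrix(tt)), 1L)
})

test_that("cell map io round-trips", {
  cells <- data.frame(case_id = "c1", x_um = c(1.5, 2.5), y_um = c(0, 1),
                      cell_type = c("M", "N"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_map(cells, path)
  expect_equal(read_cell_map(path), cells)
  expect_error(validate_cells(data.frame(x_um = 1, y_um = 1,
                                         cell_type = "Z"),
                              require_case_id = FALSE),
               "unknown cell type")
})
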