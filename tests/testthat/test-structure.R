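toy_records <- function() {
  rbind(
    data.frame(record = "ATOM", serial = 1:8, name = "CA", resname = "ALA",
               chain = "A", resseq = 1:8, x = seq(10, 80, 10), y = 0, z = 0,
               element = "C", stringsAsFactors = FALSE),
    data.frame(record = "HETATM", serial = 9:28, name = "C1", resname = "RET",
               chain = "A", resseq = 900, x = seq(0.1, 2, 0.1), y = 1, z = 2,
               element = "C", stringsAsFactors = FALSE))
}

test_that("fixed-column parsing keeps ATOM and HETATM records with flags", {
  model <- read_structure(text = make_pdb_lines(toy_records()))
  expect_equal(nrow(model$atoms), 28)
  expect_equal(sum(model$atoms$is_hetero), 20)
  expect_equal(sum(model$atoms$is_ligand), 20)
})

test_that("only the first MODEL block is kept, with a warning", {
  recs <- toy_records()
  lines <- c("MODEL        1", make_pdb_lines(recs), "ENDMDL",
             "MODEL        2", make_pdb_lines(recs), "ENDMDL")
  expect_warning(model <- read_structure(text = lines), "MODEL")
  expect_equal(nrow(model$atoms), 28)
})

test_that("altloc records other than blank/A are dropped", {
  lines <- make_pdb_lines(toy_records())
  lineB <- lines[1]; substr(lineB, 17, 17) <- "B"
  lineA <- lines[2]; substr(lineA, 17, 17) <- "A"
  model <- read_structure(text = c(lineB, lineA, lines[9:28]))
  expect_equal(sum(!model$atoms$is_hetero), 1)
})

test_that("malformed coordinates raise a line-addressed error; empty input a format error", {
  lines <- make_pdb_lines(toy_records())
  substr(lines[3], 31, 38) <- "   xx.xx"
  expect_error(read_structure(text = lines), "line 3")
  expect_error(read_structure(text = c("HEADER    TEST", "END")), "no parsable")
})

test_that("parser agrees with bio3d on a toy structure", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(make_pdb_lines(toy_records()), "END"), path)
  model <- read_structure(path)
  ref <- suppressWarnings(bio3d::read.pdb(path))
  expect_equal(nrow(model$atoms), nrow(ref$atom))
  expect_equal(model$atoms$x, ref$atom$x)
  expect_equal(model$atoms$residue_seq, ref$atom$resno)
})

test_that("minimum ligand distance follows Euclidean geometry", {
  recs <- data.frame(record = c("ATOM", "HETATM"), serial = 1:2,
                     name = c("CA", "C1"), resname = c("ALA", "RET"),
                     chain = "A", resseq = c(1, 900),
                     x = c(0, 3), y = c(0, 4), z = c(0, 0),
                     element = "C", stringsAsFactors = FALSE)
  model <- read_structure(text = make_pdb_lines(recs))
  expect_equal(min_ligand_distance(model, "A:1"), 5)
  # coincident atoms
  recs$x[2] <- 0; recs$y[2] <- 0
  model0 <- read_structure(text = make_pdb_lines(recs))
  expect_equal(min_ligand_distance(model0, "A:1"), 0)
})

test_that("min_ligand_distance equals the exhaustive all-pairs minimum", {
  set.seed(5)
  recs <- rbind(
    data.frame(record = "ATOM", serial = 1:20, name = "CA", resname = "ALA",
               chain = "A", resseq = 1, x = rnorm(20, 5), y = rnorm(20),
               z = rnorm(20), element = "C", stringsAsFactors = FALSE),
    data.frame(record = "HETATM", serial = 21:30, name = "C1", resname = "RET",
               chain = "A", resseq = 900, x = rnorm(10), y = rnorm(10),
               z = rnorm(10), element = "C", stringsAsFactors = FALSE))
  model <- read_structure(text = make_pdb_lines(recs))
  a <- model$atoms[!model$atoms$is_ligand, ]; b <- model$atoms[model$atoms$is_ligand, ]
  brute <- min(sapply(seq_len(nrow(a)), function(i)
    sqrt((a$x[i] - b$x)^2 + (a$y[i] - b$y)^2 + (a$z[i] - b$z)^2)))
  expect_equal(min_ligand_distance(model, "A:1"), brute)
})

test_that("missing ligand raises a no-ligand error", {
  recs <- toy_records()[1:8, ]
  model <- read_structure(text = make_pdb_lines(recs))
  expect_error(binding_pocket(model), "no ligand")
  expect_error(min_ligand_distance(model, "A:1"), "no ligand")
})

test_that("pocket membership includes the boundary at exactly the cutoff", {
  recs <- rbind(
    data.frame(record = "ATOM", serial = 1:3, name = "CA", resname = "ALA",
               chain = "A", resseq = 1:3, x = c(3.5, 4.0, 4.5), y = 0, z = 0,
               element = "C", stringsAsFactors = FALSE),
    data.frame(record = "HETATM", serial = 4, name = "C1", resname = "RET",
               chain = "A", resseq = 900, x = 0, y = 0, z = 0,
               element = "C", stringsAsFactors = FALSE))
  pocket <- binding_pocket(read_structure(text = make_pdb_lines(recs)), cutoff = 4.0)
  expect_equal(pocket$residue_seq[pocket$in_pocket], c(1, 2))
})

test_that("a far ligand yields an empty pocket", {
  recs <- toy_records()
  recs$x[recs$record == "HETATM"] <- recs$x[recs$record == "HETATM"] + 500
  pocket <- binding_pocket(read_structure(text = make_pdb_lines(recs)))
  expect_false(any(pocket$in_pocket))
})

test_that("pocket detection matches truth and brute force on seeded toy structures", {
  for (seed in 1:10) {
    n <- 12
    planted <- sort(sample(seq_len(n), sample(0:6, 1)))
    gen <- generate_toy_structure(n, planted, cutoff = 4.0, seed = seed)
    model <- read_structure(text = gen$pdb)
    pocket <- binding_pocket(model, cutoff = 4.0)
    expect_equal(pocket$residue_seq[pocket$in_pocket], gen$truth)
    expect_setequal(sprintf("A:%d", pocket$residue_seq[pocket$in_pocket]),
                    brute_force_pocket(model, 4.0))
  }
})

test_that("pocket grows monotonically with the cutoff", {
  gen <- generate_toy_structure(10, planted_pocket = c(2, 5, 8), seed = 3)
  model <- read_structure(text = gen$pdb)
  prev <- character(0)
  for (cutoff in c(0.5, 2, 4, 8, 60)) {
    p <- binding_pocket(model, cutoff = cutoff)
    now <- paste0(p$chain, p$residue_seq)[p$in_pocket]
    expect_true(all(prev %in% now))
    prev <- now
  }
})

test_that("pocket membership and distances are rigid-motion invariant", {
  gen <- generate_toy_structure(8, planted_pocket = c(1, 4), seed = 9)
  model <- read_structure(text = gen$pdb)
  p0 <- binding_pocket(model)
  # rotate about z by 1 radian and translate
  th <- 1; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + 11.3; model$atoms$y <- xyz[, 2] - 4.2
  model$atoms$z <- xyz[, 3] + 0.7
  p1 <- binding_pocket(model)
  expect_equal(p1$in_pocket, p0$in_pocket)
  expect_equal(p1$min_distance, p0$min_distance, tolerance = 1e-9)
})

test_that("excluding hydrogens can only keep or increase minimum distances", {
  recs <- rbind(
    data.frame(record = "ATOM", serial = 1:2, name = c("CA", "H1"),
               resname = "ALA", chain = "A", resseq = 1,
               x = c(5, 2), y = 0, z = 0, element = c("C", "H"),
               stringsAsFactors = FALSE),
    data.frame(record = "HETATM", serial = 3, name = "C1", resname = "RET",
               chain = "A", resseq = 900, x = 0, y = 0, z = 0, element = "C",
               stringsAsFactors = FALSE))
  model <- read_structure(text = make_pdb_lines(recs))
  expect_equal(min_ligand_distance(model, "A:1", "include_h"), 2)
  expect_equal(min_ligand_distance(model, "A:1", "exclude_h"), 5)
})
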