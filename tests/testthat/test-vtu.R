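test_that("VTU writer emits a well-formed file that round-trips", {
  skip_if_not_installed("xml2")
  res <- run_cached("single", "stiff")
  mesh <- res$mesh
  path <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(mesh, path, field = res$field)

  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, "//Piece")
  n_cells <- nrow(mesh$tets) + nrow(mesh$tris) + nrow(mesh$bars)
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")),
               nrow(mesh$nodes))
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")), n_cells)

  grab <- function(xpath) {
    nd <- xml2::xml_find_first(doc, xpath)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- matrix(grab("//Points/DataArray"), ncol = 3, byrow = TRUE)
  expect_equal(pts, unname(mesh$nodes), tolerance = 1e-15)
  conn <- grab("//DataArray[@Name='connectivity']")
  expect_equal(conn[1:4] + 1, mesh$tets[1, ])
  types <- grab("//DataArray[@Name='types']")
  expect_equal(sum(types == 10), nrow(mesh$tets))
  expect_equal(sum(types == 5), nrow(mesh$tris))
  expect_equal(sum(types == 3), nrow(mesh$bars))
  hmh <- grab("//DataArray[@Name='hmh']")
  expect_equal(hmh[seq_len(nrow(mesh$tets))], unname(res$field$tet_hmh),
               tolerance = 1e-15)
  disp <- matrix(grab("//PointData/DataArray[@Name='displacement']"),
                 ncol = 3, byrow = TRUE)
  expect_equal(as.vector(t(disp)), res$field$u, tolerance = 1e-15)
})

test_that("group scene VTU carries all 18 distinct cell ids", {
  skip_if_not_installed("xml2")
  mesh <- fixture("mesh_group_FALSE", function()
    build_scene(config_to_scene_t(test_config("group"))))
  path <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(mesh, path)
  doc <- xml2::read_xml(path)
  ids <- scan(text = xml2::xml_text(
    xml2::xml_find_first(doc, "//DataArray[@Name='cell_id']")),
    quiet = TRUE)
  expect_setequal(unique(ids[ids > 0]), 1:18)
})

test_that("mismatched field arrays are refused", {
  res <- run_cached("single", "stiff")
  bad <- res$field
  bad$tet_hmh <- bad$tet_hmh[-1]
  bad$tet_stress <- bad$tet_stress[-1, ]
  expect_error(write_vtu(res$mesh, tempfile(fileext = ".vtu"), field = bad),
               "match")
})
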