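test_that("CSV localization tables round-trip bit-identically", {
    lt <- LocalizationTable(frame = c(0L, 1L, 3L),
                            x = c(10.25, 20.125, 1 / 3 * 1e4),
                            y = c(5.5, 6.75, sqrt(2) * 1e3),
                            intensity = c(100, 90.5, 80.125),
                            channel = "green", pixelSize = 100)
    path <- withr::local_tempfile(fileext = ".csv")
    writeLocalizations(lt, path, "csv")
    back <- readLocalizations(path, "csv", channel = "green")
    expect_identical(locData(back), locData(lt))
    expect_identical(nFrames(back), nFrames(lt))
})

test_that("header-only CSV gives an empty table with zero frames", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines("frame,x,y,intensity", path)
    lt <- readLocalizations(path, "csv")
    expect_identical(nLocalizations(lt), 0L)
    expect_identical(nFrames(lt), 0L)
})

test_that("missing columns and missing files are reported by name", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("frame,x,y", "0,1,2"), path)
    expect_error(readLocalizations(path, "csv"), "intensity")
    expect_error(readLocalizations(tempfile(), "csv"), "not found")
})

test_that("extra CSV columns are ignored on read", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("frame,x,y,intensity,sigma", "0,1,2,3,9"), path)
    lt <- readLocalizations(path, "csv")
    expect_identical(locData(lt)$x, 1)
})

test_that("HDF5 dialect round-trips a large simulator table", {
    sim <- simulateRecording(simConfig(nComplexes = 2500L, nBeads = 8L,
                                       nFramesMarker = 400L,
                                       nFramesIndicator = 100L,
                                       minSeparation = 0,
                                       seed = 7L))
    lt <- sim$marker
    expect_gt(nLocalizations(lt), 10000)
    path <- withr::local_tempfile(fileext = ".h5")
    writeLocalizations(lt, path, "hdf5")
    back <- readLocalizations(path, "hdf5")
    expect_identical(locData(back)$frame, locData(lt)$frame)
    expect_equal(locData(back)$x, locData(lt)$x, tolerance = 1e-9)
    expect_equal(locData(back)$y, locData(lt)$y, tolerance = 1e-9)
    expect_identical(locData(back)$intensity, locData(lt)$intensity)
    expect_identical(channelLabel(back), "green")
    expect_identical(nFrames(back), nFrames(lt))
    expect_equal(pixelSize(back), pixelSize(lt))
})

test_that("HDF5 dialect stores pixels: coordinates scale with pixel size", {
    lt <- LocalizationTable(frame = 0:1, x = c(100, 250), y = c(50, 75),
                            intensity = c(1, 2), pixelSize = 100)
    path <- withr::local_tempfile(fileext = ".h5")
    writeLocalizations(lt, path, "hdf5")
    px <- rhdf5::h5read(path, "locs/x")
    expect_equal(as.numeric(px), c(1, 2.5))      # pixels on disk
    ## a pixel-unit file read with pixel_size_nm = 100 gives 100x pixels
    back <- readLocalizations(path, "hdf5")
    expect_equal(locData(back)$x, as.numeric(px) * 100)
})

test_that("MATLAB dialect round-trips with metadata", {
    lt <- LocalizationTable(frame = c(0L, 2L, 2L),
                            x = c(1.5, 2.25, 1e4 / 3),
                            y = c(-4.5, 0.125, 8.75),
                            intensity = c(10, 20, 30),
                            channel = "red", pixelSize = 80, nFrames = 5L)
    path <- withr::local_tempfile(fileext = ".mat")
    writeLocalizations(lt, path, "matlab")
    back <- readLocalizations(path, "matlab")
    expect_identical(locData(back), locData(lt))
    expect_identical(channelLabel(back), "red")
    expect_identical(nFrames(back), 5L)
    expect_equal(pixelSize(back), 80)
})

test_that("unreadable MATLAB containers raise an I/O error", {
    path <- withr::local_tempfile(fileext = ".mat")
    writeLines("this is not a MAT file", path)
    expect_error(readLocalizations(path, "matlab"), "bridge failed")
})

test_that("CA parameter files round-trip to full float precision", {
    m <- CAModel(slopeX = 1 / 3 * 1e-2, interceptX = sqrt(2),
                 slopeY = -2.5e-4, interceptY = -7.125)
    path <- withr::local_tempfile(fileext = ".csv")
    writeCAParams(m, path)
    back <- readCAParams(path)
    expect_identical(back@slopeX, m@slopeX)
    expect_identical(back@interceptX, m@interceptX)
    expect_identical(back@slopeY, m@slopeY)
    expect_identical(back@interceptY, m@interceptY)
    expect_identical(back@referenceChannel, "green")
    expect_identical(back@correctedChannel, "red")
})

test_that("a zero CA model is the identity correction", {
    zero <- CAModel()
    path <- withr::local_tempfile(fileext = ".csv")
    writeCAParams(zero, path)
    back <- readCAParams(path)
    lt <- LocalizationTable(0:2, c(1, 2, 3), c(4, 5, 6), c(1, 1, 1))
    expect_identical(locData(applyChromaticAberration(lt, back)),
                     locData(lt))
})

test_that("malformed CA parameter files raise a format error", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("reference_channel,corrected_channel,slope_x,intercept_x",
                 "green,red,0,0"), path)
    expect_error(readCAParams(path), "slope_y")
})

test_that("ratio tables round-trip and preserve row order", {
    tab <- simulateRatioTable(1:4, recordingsPerState = 3L,
                              complexesPerRecording = 100L, seed = 3L)
    expect_identical(nrow(tab), 12L)
    path <- withr::local_tempfile(fileext = ".csv")
    writeRatioTable(tab, path, comments = c("seed: 3"))
    back <- readRatioTable(path)
    expect_identical(back$recording_id, tab$recording_id)
    expect_identical(back$n_marker, tab$n_marker)
    expect_identical(back$n_coloc, tab$n_coloc)
    expect_equal(back$ratio, tab$ratio, tolerance = 1e-12)
    expect_identical(back$known_state, tab$known_state)
})

test_that("ratio tables violating N_MF <= N_M are rejected on read", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("recording_id,n_marker,n_coloc,ratio", "rec1,4,5,1.25"),
               path)
    expect_error(readRatioTable(path), "n_coloc <= n_marker")
    writeLines(c("recording_id,n_marker,n_coloc,ratio", "rec1,4,3,0.9"),
               path)
    expect_error(readRatioTable(path), "ratio must equal")
})

test_that("single-row ratio tables survive a write/read cycle", {
    tab <- data.frame(recording_id = "rec1", n_marker = 4L, n_coloc = 3L,
                      ratio = 0.75)
    path <- withr::local_tempfile(fileext = ".csv")
    writeRatioTable(tab, path)
    expect_equal(readRatioTable(path), tab)
})
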