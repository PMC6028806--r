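test_that("SBML export is structurally conformant Level 3", {
  f <- tempfile(fileext = ".sbml")
  export_sbml(make_binding_model(), f)
  expect_length(validate_sbml_structure(f), 0L)
  unlink(f)
})

test_that("native -> SBML -> native round trip preserves structure and rates", {
  for (maker in list(make_binding_model, make_cascade_model,
                     function() make_translation_fixture()$model)) {
    m <- maker()
    f <- tempfile(fileext = ".sbml")
    export_sbml(m, f)
    m2 <- read_sbml_model(f)
    expect_length(validate_model(m2), 0L)
    expect_setequal(nm0(m2$pools), nm0(m$pools))
    expect_setequal(nm0(m2$reactions), nm0(m$reactions))
    expect_setequal(nm0(m2$enzymes), nm0(m$enzymes))
    expect_setequal(m2$groups, m$groups)
    for (rp in names(m$reactions)) {
      expect_equal(m2$reactions[[rp]]$Kf, m$reactions[[rp]]$Kf, tolerance = 1e-12)
      expect_equal(m2$reactions[[rp]]$Kb, m$reactions[[rp]]$Kb, tolerance = 1e-12)
    }
    for (ep in names(m$enzymes)) {
      expect_equal(m2$enzymes[[ep]]$Km, m$enzymes[[ep]]$Km, tolerance = 1e-12)
      expect_equal(m2$enzymes[[ep]]$kcat, m$enzymes[[ep]]$kcat, tolerance = 1e-12)
    }
    for (pp in names(m$pools)) {
      expect_equal(m2$pools[[pp]]$concInit, m$pools[[pp]]$concInit, tolerance = 1e-12)
      expect_identical(m2$pools[[pp]]$buffered, m$pools[[pp]]$buffered)
    }
    unlink(f)
  }
})

test_that("buffered pools map to boundary-condition species", {
  m <- make_binding_model()
  m$pools[["/binding/L"]]$buffered <- TRUE
  f <- tempfile(fileext = ".sbml")
  export_sbml(m, f)
  doc <- xml2::read_xml(f)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  sp <- xml2::xml_find_all(doc, "//s:species", ns)
  bc <- xml2::xml_attr(sp, "boundaryCondition")
  names(bc) <- xml2::xml_attr(sp, "name")
  expect_identical(bc[["/binding/L"]], "true")
  expect_identical(bc[["/binding/R"]], "false")
  m2 <- read_sbml_model(f)
  expect_true(m2$pools[["/binding/L"]]$buffered)
  unlink(f)
})

test_that("time-series stimuli export as SBML events", {
  sched <- stimulus_schedule(list(
    list(time = 10, entity = "/binding/L", field = "conc", value = 2),
    list(time = 50, entity = "/binding/L", field = "conc", value = 0)))
  f <- tempfile(fileext = ".sbml")
  export_sbml(make_binding_model(), f, stimuli = sched)
  doc <- xml2::read_xml(f)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  expect_length(xml2::xml_find_all(doc, "//s:event", ns), 2L)
  unlink(f)
})

test_that("unrecognized rate laws raise an error naming the reaction", {
  f <- tempfile(fileext = ".sbml")
  export_sbml(make_binding_model(), f)
  txt <- readLines(f)
  ## strip the canonical local parameters so the law is unrecognizable
  txt <- gsub('id="Kf"', 'id="k_weird"', txt, fixed = TRUE)
  f2 <- tempfile(fileext = ".sbml")
  writeLines(txt, f2)
  expect_error(read_sbml_model(f2), "unsupported kinetic law.*bind")
  unlink(c(f, f2))
})

test_that("foreign flat SBML without groups reads as entities under root", {
  f <- tempfile(fileext = ".sbml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="flat"><listOfCompartments>',
    '<compartment id="c" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A" compartment="c" initialConcentration="1" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
    '<species id="B" compartment="c" initialConcentration="0" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="r1" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>',
    '<kineticLaw><listOfLocalParameters>',
    '<localParameter id="Kf" value="0.25"/><localParameter id="Kb" value="0"/>',
    '</listOfLocalParameters></kineticLaw></reaction>',
    '</listOfReactions></model></sbml>'), f)
  m <- read_sbml_model(f)
  expect_setequal(names(m$pools), c("/A", "/B"))
  expect_equal(m$reactions[["/r1"]]$Kf, 0.25)
  expect_length(validate_model(m), 0L)
  unlink(f)
})
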