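Package: tgquant
Title: Triacylglycerol Quantitation and Edible-Oil Adulteration Detection
    from High-Temperature GC-FID Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triacylglycerol (TG) analysis by high-temperature gas
    chromatography with flame-ionization detection (HTGC-FID): TG nomenclature
    parsing with carbon number (CN), double-bond number (DB) and equivalent
    carbon number (ECN = CN - 2*DB) descriptors; peak identification from
    relative retention times via a log(rrt)-versus-DB interpolation chart
    built from monoacid standards; internal-standard quantitation with
    relative response factors; method-validation statistics (recovery, RSD,
    intraday/interday precision, LOD/LOQ); and detection of rapeseed/olive
    oil blending from indicator TGs with linear mixing-model fraction
    estimation. Includes a seeded synthetic-chromatogram generator so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
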