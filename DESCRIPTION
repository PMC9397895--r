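Package: musclevol
Title: Muscle Volume Estimation from Serial MRI Cross-Sectional Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Estimation of skeletal muscle volume from serial anatomical
    cross-sectional areas (ACSA) segmented on axial MRI, with the cylindrical
    (Cavalieri) and truncated-cone (frustum) equations. Supports restricted
    region-of-interest handling between anatomical landmarks, slice-interval
    subsampling experiments, and the associated agreement statistics
    (absolute and relative error against a 1 cm reference, Bland-Altman bias
    and limits of agreement, two-way mixed intraclass correlation, Pearson
    correlation). Includes a synthetic quadriceps phantom generator with
    analytically known volumes for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, RNifti, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
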