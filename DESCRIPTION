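Package: lesionmap
Title: Lesion Overlay, Subtraction and Indirect Disconnection Mapping for Stroke Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based lesion mapping for cohorts of binary stroke lesion
    masks. Builds cohort lesion overlays (voxelwise counts and proportions),
    extracts a thresholded common-lesion map, computes a between-cohort
    subtraction map with a max-difference threshold rule and binarizes it,
    quantifies percent overlap of any binary map with the parcels of a
    labeled atlas, and estimates indirect white-matter disconnection by
    intersecting lesions with a normative streamline tract atlas. A seeded
    synthetic-data module generates lesion cohorts, parcellations and tract
    atlases with known ground truth so the full pipeline can be exercised
    and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
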