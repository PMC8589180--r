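Package: octamap
Title: Quantifying Overlap of Deep Capillary Telangiectasia with
    Photoreceptor Disruption on En-Face OCT/OCTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the spatial relationship between deep
    capillary plexus (DCP) telangiectasia and graded photoreceptor
    disruption (interdigitation-zone attenuation, interdigitation-zone
    loss and ellipsoid-zone loss) on en-face OCT angiography of the
    macula. Provides local Phansalkar and maximum-entropy (Kapur)
    thresholding with hole filling for partially automatic vessel
    circumscription, nested-region decomposition into exclusive
    disruption classes with physical areas and percent overlaps,
    elastic longitudinal registration of follow-up scans via the
    superficial capillary plexus, chance-normalized predictive values
    (rPPV/rNPV) of baseline interdigitation-zone loss for new
    ellipsoid-zone loss, cohort statistics (Spearman correlation,
    intraclass correlation, generalized estimating equations with
    exchangeable working correlation), and a synthetic scene generator
    that emulates the imaging study so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
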