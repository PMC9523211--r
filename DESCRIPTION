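Package: epwave
Type: Package
Title: Automated Quantification of Endometrial Peristalsis in Cine Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated measurement of endometrial peristalsis in cine
    transvaginal ultrasound. Tracks a grid of feature points inside a
    user-drawn endometrial region with sparse pyramidal Lucas-Kanade optical
    flow, converts lagged row-curvature variation into a normalized salience
    field, renders motion-amplified colour overlays, builds a directional
    motion graph, and reports the number, direction (cervix-to-fundus,
    fundus-to-cervix, or mixed), intensity, and velocity of peristaltic
    waves. Includes a seeded speckle-phantom generator producing clips with
    known travelling waves for validation, and observer-agreement statistics
    (intraclass correlation, percent agreement, paired nonparametric tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    tiff,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
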