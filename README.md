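# periobone

Quantify alveolar bone loss and assign per-tooth periodontal prognoses
from segmented dental panoramic radiographs.

Periodontitis destroys the alveolar bone that supports the teeth, and the
radiographic sign of that destruction is the apical migration of the
alveolar bone crest away from the cemento-enamel junction (CEJ). Reading
this off a panoramic radiograph by hand is slow and subjective. `periobone`
implements everything downstream of a segmentation model (e.g. a
YOLO-family network trained on LabelMe polygon annotations): it turns tooth
polygons and CEJ-to-bone-level polygons into landmark geometry, millimeter
distances, bone-loss percentages and prognosis levels, and evaluates the
segmentations themselves. It is aimed at dental-imaging researchers who
have (or are building) a detector and need the measurement, staging and
evaluation layers around it.

## The measurement model

For each tooth a long axis is fitted from the area moments of its polygon.
Along that axis three landmarks are taken per site: the CEJ (**A**), the
alveolar bone crest (**B**) and the root apex (**C**). With a device
calibration (mm per pixel) and the ~2 mm biologic width *w* separating a
healthy crest from the CEJ, the percentage of bone loss at a site is

```
bone loss (%) = 100 × (AB − w) / (AC − w),   w = 2 mm
```

clamped to [0, 100]. A site whose CEJ-to-crest gap exceeds 2 mm is flagged
abnormal. Each tooth is scored by its most severe site, and the bone
*support* (100 − loss) maps onto the five prognosis levels of the Thai
Association of Periodontology: Good (> 75 %), Fair/Poor (50–75 %, split by
probing depth when clinical data are supplied), Questionable (25–50 %) and
Hopeless (< 25 %).

The evaluation suite reproduces the standard detection numbers: exact
polygon IoU, greedy confidence-ordered matching, precision / sensitivity /
specificity / accuracy / F1 from confusion matrices counted on a
fixed-size cell grid (the unit that makes true negatives countable), and
average precision at IoU 0.5 (mAP50, all-point interpolation).

Because clinical radiographs cannot be redistributed, the package ships a
synthetic-scene generator: simplified teeth with fully known CEJ / crest /
apex geometry, bone crests placed by inverting the formula above, and an
oracle detector returning the exact polygons — so the entire pipeline runs
and is tested with no clinical data and no trained network.

## Worked example

```r
library(periobone)

# a 6-tooth synthetic scene with known per-side bone loss
scene <- generate_scene(n_teeth = 6, loss = "uniform",
                        loss_range = c(0, 90), seed = 7)
write_scene_labelme(scene, "scene7.json", image_path = "scene7.png")
write_image(render_scene(scene), "scene7.png")

res <- analyze(image_path = "scene7.png",
               annotations_path = "scene7.json",
               out_path = "report7.csv",
               config = periobone_config(mm_per_pixel = 0.1))
res$teeth
#> # A tibble: 6 × 8
#>   tooth_id n_sites worst_side percent_bone_loss bone_support_percent
#>   <chr>      <int> <chr>                  <dbl>                <dbl>
#> 1 31             2 distal                  41.1                 58.9
#> 2 32             2 distal                  72.0                 28.0
#> 3 33             2 mesial                  76.2                 23.8
#> 4 41             2 distal                  75.5                 24.5
#> 5 42             2 distal                  71.2                 28.8
#> 6 43             2 mesial                  61.2                 38.8
res$greatest
#> # A tibble: 1 × 2
#>   tooth_id percent_bone_loss
#> 1 33                    76.2
```

Each row is one tooth: `percent_bone_loss` is the worst of its mesial and
distal sites, `bone_support_percent` its complement, and the prognosis
column (Fair for tooth 31, Questionable for 43, Hopeless for 33, …) follows
the support bands above. Tooth 33, at 76.2 % loss, is the highlighted
worst tooth of the dentition. `report7.csv` holds the per-site table
(A and C in mm, percentage, flag, prognosis).

The same functions work on real exports: `read_image()` +
`read_labelme()` on your detector's polygons, with the device's
`mm_per_pixel` in the config. `labelme_to_yolo()` / `yolo_to_polygons()`
and `convert_labelme_dir()` handle training-label conversion;
`split_dataset()` produces the 70:10:20 split; `detection_metrics()`,
`make_eval_grid()` and `average_precision()` score a detector against
ground truth. A thin command-line wrapper with `enhance`, `analyze`,
`evaluate`, `simulate`, `convert`, `split` and `config` subcommands lives
at `inst/cli/periobone.R`.

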