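# Trilinear 0.5-isosurface area and enclosed-volume contributions per
# 2x2x2 binary corner configuration. Generated by data-raw/trilinear_tables.R
# (midpoint sampling, K = 160, coarea band h = 0.04); do not edit by hand.
# Bit b of the configuration index corresponds to the corner at offset
# (b & 1, (b >> 1) & 1, (b >> 2) & 1) along the (y, x, z) array axes.
.tri_area_tab <- c(
                   0,
  0.27035236966425419,
  0.27035236966425419,
  0.71952882228478654,
  0.2703523696642543,
  0.71952882228478643,
  0.70081674331937871,
  1.0406816656265638,
  0.2703523696642543,
  0.70081674331937871,
  0.71952882228478643,
  1.0406816656265638,
  0.71952882228478643,
  1.0406816656265638,
  1.0406816656265638,
  0.93749999999998379,
  0.2703523696642543,
  0.7195288222847791,
  0.70081674331936361,
  1.0406816656265718,
  0.70081674331936383,
  1.0406816656265718,
  1.2971392297871358,
  1.2177978574885935,
  0.54471413126069856,
  1.1393388990402278,
  1.1393388990402331,
  1.2440340462521768,
  1.1393388990402331,
  1.2440340462521773,
  1.4943426875003309,
  1.0406816656265638,
  0.2703523696642543,
  0.70081674331936361,
  0.7195288222847791,
  1.0406816656265718,
  0.54471413126069856,
  1.1393388990402331,
  1.1393388990402278,
  1.2440349610321473,
  0.70081674331936383,
  1.2971392297871358,
  1.0406816656265718,
  1.2177978574885935,
  1.1393388990402331,
  1.4943426875003309,
  1.2440429580172667,
  1.0406816656265638,
  0.71952882228478643,
  1.0406816656265716,
  1.0406816656265716,
              0.9375,
  1.1393388990402331,
  1.2440386366221861,
  1.4943426875003332,
  1.0406816656265718,
  1.1393388990402331,
  1.4943426875003332,
  1.2440394355386308,
  1.0406816656265718,
  1.6825124938168523,
  1.1393388990402329,
  1.1393388990402329,
  0.71952882228478654,
  0.27035236966425419,
  0.7008167433193635,
  0.54471413126069845,
  1.1393388990402331,
  0.7195288222847791,
  1.0406816656265716,
   1.139338899040228,
  1.2440331051032842,
  0.70081674331936361,
  1.2971392297871354,
  1.1393388990402331,
  1.4943426875003309,
  1.0406816656265716,
  1.2177978574885933,
  1.2440429580172667,
  1.0406816656265638,
  0.71952882228478643,
  1.0406816656265716,
  1.1393388990402331,
  1.2440386366221861,
  1.0406816656265718,
              0.9375,
  1.4943426875003332,
  1.0406816656265718,
  1.1393388990402329,
  1.4943426875003332,
  1.6825124938168523,
  1.1393388990402329,
  1.2440394355386308,
  1.0406816656265716,
  1.1393388990402331,
  0.71952882228478643,
  0.70081674331937871,
  1.2971392297871354,
   1.139338899040228,
  1.4943426875003332,
  1.1393388990402278,
  1.4943426875003332,
  1.6825124938168483,
  1.1393388990402278,
  1.2971392297871358,
  1.8881063163273515,
  1.4943426875003332,
  1.2971392297871358,
  1.4943426875003332,
  1.2971392297871354,
   1.139338899040228,
  0.70081674331937871,
  1.0406816656265641,
  1.2177978574885933,
  1.2440356289107877,
  1.0406816656265716,
  1.2440340188795804,
  1.0406816656265716,
   1.139338899040228,
  0.7195288222847791,
  1.4943426875003309,
  1.2971392297871354,
  1.1393388990402331,
  0.70081674331936361,
  1.1393388990402331,
  0.7008167433193635,
  0.54471413126069845,
  0.27035236966425419,
  0.27035236966425419,
  0.54471413126069845,
  0.7008167433193635,
  1.1393388990402331,
  0.70081674331936361,
  1.1393388990402331,
  1.2971392297871354,
  1.4943426875003309,
  0.7195288222847791,
   1.139338899040228,
  1.0406816656265716,
    1.24402771889687,
  1.0406816656265716,
  1.2440277188968702,
  1.2177978574885933,
  1.0406816656265638,
  0.70081674331937871,
   1.139338899040228,
  1.2971392297871354,
  1.4943426875003332,
  1.2971392297871358,
  1.4943426875003332,
  1.8881063163273515,
  1.2971392297871358,
  1.1393388990402278,
  1.6825124938168483,
  1.4943426875003332,
  1.1393388990402278,
  1.4943426875003332,
   1.139338899040228,
  1.2971392297871354,
  0.70081674331937871,
  0.71952882228478643,
  1.1393388990402331,
  1.0406816656265716,
  1.2440196864781248,
  1.1393388990402329,
  1.6825124938168523,
  1.4943426875003332,
  1.1393388990402329,
  1.0406816656265718,
  1.4943426875003332,
              0.9375,
  1.0406816656265718,
  1.2440348424022496,
  1.1393388990402331,
  1.0406816656265716,
  0.71952882228478643,
  1.0406816656265641,
  1.2440277956936663,
  1.2177978574885933,
  1.0406816656265716,
  1.4943426875003309,
  1.1393388990402331,
  1.2971392297871354,
  0.70081674331936361,
  1.2440198519816581,
   1.139338899040228,
  1.0406816656265716,
  0.7195288222847791,
  1.1393388990402331,
  0.54471413126069845,
  0.7008167433193635,
  0.27035236966425419,
  0.71952882228478654,
  1.1393388990402329,
  1.1393388990402329,
  1.6825124938168523,
  1.0406816656265718,
  1.2440196864781248,
  1.4943426875003332,
  1.1393388990402331,
  1.0406816656265718,
  1.4943426875003332,
  1.2440348424022496,
  1.1393388990402331,
              0.9375,
  1.0406816656265716,
  1.0406816656265716,
  0.71952882228478643,
  1.0406816656265638,
  1.2440277956936658,
  1.4943426875003309,
  1.1393388990402331,
  1.2177978574885935,
  1.0406816656265718,
  1.2971392297871358,
  0.70081674331936383,
  1.2440198519816579,
  1.1393388990402278,
  1.1393388990402331,
  0.54471413126069856,
  1.0406816656265718,
  0.7195288222847791,
  0.70081674331936361,
  0.2703523696642543,
  1.0406816656265638,
  1.4943426875003309,
  1.2440464131111515,
  1.1393388990402331,
  1.2440313922492183,
  1.1393388990402331,
  1.1393388990402278,
  0.54471413126069856,
  1.2177978574885935,
  1.2971392297871358,
  1.0406816656265718,
  0.70081674331936383,
  1.0406816656265718,
  0.70081674331936361,
  0.7195288222847791,
  0.2703523696642543,
  0.93749999999998379,
  1.0406816656265638,
  1.0406816656265638,
  0.71952882228478643,
  1.0406816656265638,
  0.71952882228478643,
  0.70081674331937871,
  0.2703523696642543,
  1.0406816656265638,
  0.70081674331937871,
  0.71952882228478643,
  0.2703523696642543,
  0.71952882228478643,
  0.27035236966425419,
  0.27035236966425419,
                   0
)

.tri_vol_tab <- c(
                   0,
     0.0333134765625,
     0.0333134765625,
  0.15355468750000001,
     0.0333134765625,
  0.15355468750000001,
  0.088762695312500001,
  0.31525219726562498,
     0.0333134765625,
  0.088762695312500001,
  0.15355468750000001,
  0.31525219726562498,
  0.15355468750000001,
  0.31525219726562498,
  0.31525219726562498,
                 0.5,
     0.0333134765625,
  0.15355468750000001,
  0.088762695312500001,
  0.31525219726562498,
  0.088762695312500001,
  0.31525219726562498,
  0.18947094726562499,
                 0.5,
  0.068640136718749994,
  0.23188354492187499,
  0.23188354492187499,
  0.50000830078125003,
  0.23188354492187499,
  0.50000830078125003,
                 0.5,
  0.68474780273437497,
     0.0333134765625,
  0.088762695312500001,
  0.15355468750000001,
  0.31525219726562498,
  0.068640136718749994,
  0.23188354492187499,
  0.23188354492187499,
  0.50000830078125003,
  0.088762695312500001,
  0.18947094726562499,
  0.31525219726562498,
                 0.5,
  0.23188354492187499,
                 0.5,
  0.50000781250000004,
  0.68474780273437497,
  0.15355468750000001,
  0.31525219726562498,
  0.31525219726562498,
                 0.5,
  0.23188354492187499,
  0.50000805664062498,
                 0.5,
  0.68474780273437497,
  0.23188354492187499,
                 0.5,
  0.50000952148437505,
  0.68474780273437497,
                 0.5,
  0.76811645507812498,
  0.76811645507812498,
  0.84644531249999999,
     0.0333134765625,
  0.088762695312500001,
  0.068640136718749994,
  0.23188354492187499,
  0.15355468750000001,
  0.31525219726562498,
  0.23188354492187499,
  0.50000805664062498,
  0.088762695312500001,
  0.18947094726562499,
  0.23188354492187499,
                 0.5,
  0.31525219726562498,
                 0.5,
  0.50000781250000004,
  0.68474780273437497,
  0.15355468750000001,
  0.31525219726562498,
  0.23188354492187499,
  0.50000805664062498,
  0.31525219726562498,
                 0.5,
                 0.5,
  0.68474780273437497,
  0.23188354492187499,
                 0.5,
                 0.5,
  0.76811645507812498,
  0.50000952148437505,
  0.68474780273437497,
  0.76811645507812498,
  0.84644531249999999,
  0.088762695312500001,
  0.18947094726562499,
  0.23188354492187499,
                 0.5,
  0.23188354492187499,
                 0.5,
                 0.5,
  0.76811645507812498,
  0.18947094726562499,
                 0.5,
                 0.5,
  0.81052905273437503,
                 0.5,
  0.81052905273437503,
  0.76811645507812498,
  0.91123730468749997,
  0.31525219726562498,
                 0.5,
    0.50000927734375,
  0.68474780273437497,
  0.50000903320312495,
  0.68474780273437497,
  0.76811645507812498,
  0.84644531249999999,
                 0.5,
  0.81052905273437503,
  0.76811645507812498,
  0.91123730468749997,
  0.76811645507812498,
  0.91123730468749997,
  0.93135986328124998,
  0.96668652343749994,
     0.0333134765625,
  0.068640136718749994,
  0.088762695312500001,
  0.23188354492187499,
  0.088762695312500001,
  0.23188354492187499,
  0.18947094726562499,
                 0.5,
  0.15355468750000001,
  0.23188354492187499,
  0.31525219726562498,
  0.50000878906250001,
  0.31525219726562498,
  0.50000878906250001,
                 0.5,
  0.68474780273437497,
  0.088762695312500001,
  0.23188354492187499,
  0.18947094726562499,
                 0.5,
  0.18947094726562499,
                 0.5,
                 0.5,
  0.81052905273437503,
  0.23188354492187499,
                 0.5,
                 0.5,
  0.76811645507812498,
                 0.5,
  0.76811645507812498,
  0.81052905273437503,
  0.91123730468749997,
  0.15355468750000001,
  0.23188354492187499,
  0.31525219726562498,
  0.50000878906250001,
  0.23188354492187499,
                 0.5,
                 0.5,
  0.76811645507812498,
  0.31525219726562498,
                 0.5,
                 0.5,
  0.68474780273437497,
  0.50001000976562504,
  0.76811645507812498,
  0.68474780273437497,
  0.84644531249999999,
  0.31525219726562498,
    0.50000927734375,
                 0.5,
  0.68474780273437497,
                 0.5,
  0.76811645507812498,
  0.81052905273437503,
  0.91123730468749997,
  0.50000952148437505,
  0.76811645507812498,
  0.68474780273437497,
  0.84644531249999999,
  0.76811645507812498,
  0.93135986328124998,
  0.91123730468749997,
  0.96668652343749994,
  0.15355468750000001,
  0.23188354492187499,
  0.23188354492187499,
                 0.5,
  0.31525219726562498,
  0.50000878906250001,
                 0.5,
  0.76811645507812498,
  0.31525219726562498,
                 0.5,
  0.50001000976562504,
  0.76811645507812498,
                 0.5,
  0.68474780273437497,
  0.68474780273437497,
  0.84644531249999999,
  0.31525219726562498,
    0.50000927734375,
                 0.5,
  0.76811645507812498,
                 0.5,
  0.68474780273437497,
  0.81052905273437503,
  0.91123730468749997,
  0.50000952148437505,
  0.76811645507812498,
  0.76811645507812498,
  0.93135986328124998,
  0.68474780273437497,
  0.84644531249999999,
  0.91123730468749997,
  0.96668652343749994,
  0.31525219726562498,
                 0.5,
  0.50000952148437505,
  0.76811645507812498,
  0.50000952148437505,
  0.76811645507812498,
  0.76811645507812498,
  0.93135986328124998,
                 0.5,
  0.81052905273437503,
  0.68474780273437497,
  0.91123730468749997,
  0.68474780273437497,
  0.91123730468749997,
  0.84644531249999999,
  0.96668652343749994,
                 0.5,
  0.68474780273437497,
  0.68474780273437497,
  0.84644531249999999,
  0.68474780273437497,
  0.84644531249999999,
  0.91123730468749997,
  0.96668652343749994,
  0.68474780273437497,
  0.91123730468749997,
  0.84644531249999999,
  0.96668652343749994,
  0.84644531249999999,
  0.96668652343749994,
  0.96668652343749994,
                   1
)
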