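"dataset_label","tissue","time_h","conc_nmol_per_mL","sd","n","excluded","measure"
"mouse_po_synthetic","plasma",0.5,13.8381215214127,1.38381215214127,1,FALSE,"conc"
"mouse_po_synthetic","plasma",1,28.8810272321345,2.88810272321345,1,FALSE,"conc"
"mouse_po_synthetic","plasma",2,26.3602984827334,2.63602984827334,1,FALSE,"conc"
"mouse_po_synthetic","plasma",4,8.77344905382291,0.877344905382291,1,FALSE,"conc"
"mouse_po_synthetic","plasma",8,0.452305945531003,0.0452305945531003,1,FALSE,"conc"
"mouse_po_synthetic","plasma",24,4.66694073629616e-06,4.66694073629616e-07,1,FALSE,"conc"
"mouse_po_synthetic","portal_vein",0.5,43.4121341354098,4.34121341354098,1,FALSE,"conc"
"mouse_po_synthetic","portal_vein",1,61.3503707561921,6.13503707561921,1,FALSE,"conc"
"mouse_po_synthetic","portal_vein",2,39.6862667851918,3.96862667851918,1,FALSE,"conc"
"mouse_po_synthetic","portal_vein",4,7.44479668042875,0.744479668042875,1,FALSE,"conc"
"mouse_po_synthetic","portal_vein",8,0.518622165676782,0.0518622165676782,1,FALSE,"conc"
"mouse_po_synthetic","portal_vein",24,5.36619059886512e-06,5.36619059886512e-07,1,FALSE,"conc"
"mouse_po_synthetic","intestine",0.5,2236.90184109649,223.690184109649,1,FALSE,"conc"
"mouse_po_synthetic","intestine",1,2351.56342055665,235.156342055665,1,FALSE,"conc"
"mouse_po_synthetic","intestine",2,1271.28734435594,127.128734435594,1,FALSE,"conc"
"mouse_po_synthetic","intestine",4,50.4843635880265,5.04843635880265,1,FALSE,"conc"
"mouse_po_synthetic","intestine",8,2.61596170784164,0.261596170784164,1,FALSE,"conc"
"mouse_po_synthetic","intestine",24,3.33146892654277e-05,3.33146892654277e-06,1,FALSE,"conc"
"mouse_po_synthetic","liver",0.5,201.72092669242,20.172092669242,1,FALSE,"conc"
"mouse_po_synthetic","liver",1,303.975208580775,30.3975208580775,1,FALSE,"conc"
"mouse_po_synthetic","liver",2,231.522537782448,23.1522537782448,1,FALSE,"conc"
"mouse_po_synthetic","liver",4,47.8021223310958,4.78021223310958,1,FALSE,"conc"
"mouse_po_synthetic","liver",8,2.58919688257295,0.258919688257295,1,FALSE,"conc"
"mouse_po_synthetic","liver",24,2.43879252638981e-05,2.43879252638981e-06,1,FALSE,"conc"
"mouse_po_synthetic","kidney",0.5,145.05916849506,14.505916849506,1,FALSE,"conc"
"mouse_po_synthetic","kidney",1,366.740166850135,36.6740166850135,1,FALSE,"conc"
"mouse_po_synthetic","kidney",2,475.176883319727,47.5176883319727,1,FALSE,"conc"
"mouse_po_synthetic","kidney",4,76.0634331871914,7.60634331871914,1,FALSE,"conc"
"mouse_po_synthetic","kidney",8,4.40618238366731,0.440618238366731,1,FALSE,"conc"
"mouse_po_synthetic","kidney",24,5.54076300639861e-05,5.54076300639861e-06,1,FALSE,"conc"
"mouse_po_synthetic","heart",0.5,41.406382613439,4.1406382613439,1,FALSE,"conc"
"mouse_po_synthetic","heart",1,69.8167443088735,6.98167443088735,1,FALSE,"conc"
"mouse_po_synthetic","heart",2,74.7367102361456,7.47367102361456,1,FALSE,"conc"
"mouse_po_synthetic","heart",4,18.7072777507419,1.87072777507419,1,FALSE,"conc"
"mouse_po_synthetic","heart",8,0.958944082006725,0.0958944082006725,1,FALSE,"conc"
"mouse_po_synthetic","heart",24,1.22149097792766e-05,1.22149097792766e-06,1,FALSE,"conc"
"mouse_po_synthetic","muscle",0.5,24.7760035034896,2.47760035034896,1,FALSE,"conc"
"mouse_po_synthetic","muscle",1,81.1402429364846,8.11402429364846,1,FALSE,"conc"
"mouse_po_synthetic","muscle",2,139.569132922406,13.9569132922406,1,FALSE,"conc"
"mouse_po_synthetic","muscle",4,43.1876963216118,4.31876963216118,1,FALSE,"conc"
"mouse_po_synthetic","muscle",8,2.31647621548878,0.231647621548878,1,FALSE,"conc"
"mouse_po_synthetic","muscle",24,2.65718931609381e-05,2.65718931609381e-06,1,FALSE,"conc"
"mouse_po_synthetic","adipose",0.5,10.1504458886931,1.01504458886931,1,FALSE,"conc"
"mouse_po_synthetic","adipose",1,20.4906141340481,2.04906141340481,1,FALSE,"conc"
"mouse_po_synthetic","adipose",2,19.0336186775378,1.90336186775378,1,FALSE,"conc"
"mouse_po_synthetic","adipose",4,5.00061578605641,0.500061578605641,1,FALSE,"conc"
"mouse_po_synthetic","adipose",8,0.325548835193279,0.0325548835193279,1,FALSE,"conc"
"mouse_po_synthetic","adipose",24,3.92225525564922e-06,3.92225525564922e-07,1,FALSE,"conc"
"mouse_po_synthetic","brain",0.5,11.3413660237178,1.13413660237178,1,FALSE,"conc"
"mouse_po_synthetic","brain",1,24.585357483849,2.4585357483849,1,FALSE,"conc"
"mouse_po_synthetic","brain",2,23.983054130373,2.3983054130373,1,FALSE,"conc"
"mouse_po_synthetic","brain",4,5.67657343819828,0.567657343819828,1,FALSE,"conc"
"mouse_po_synthetic","brain",8,0.365166751647238,0.0365166751647238,1,FALSE,"conc"
"mouse_po_synthetic","brain",24,3.64927698263795e-06,3.64927698263795e-07,1,FALSE,"conc"
"mouse_po_synthetic","urine",24,8436.07897861663,843.607897861663,1,FALSE,"amount"
"mouse_po_synthetic","feces",24,5776.32225360447,577.632225360447,1,FALSE,"amount"
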