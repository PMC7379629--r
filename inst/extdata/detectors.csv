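name,shape,dimension_mm,description
EBT3-ROI,circular,0.25,Radiochromic film central ROI of 0.5 mm diameter
W1,circular,0.5,Exradin W1 plastic scintillator fiber r = 0.5 mm
IBA SFD diode,circular,0.3,Disk diameter 0.6 mm
IBA Razor diode,circular,0.3,Disk diameter 0.6 mm
PTW 60008 Diode P,circular,0.6,Disk diameter 1.2 mm
PTW 60012 Diode E,circular,0.6,Disk diameter 1.2 mm
PTW 60018 Diode SRS,circular,0.6,Disk diameter 1.2 mm
SN EDGE Detector,square,0.8,Square 0.8 x 0.8 mm
PTW 60019 mD,circular,1.1,Disk diameter 2.2 mm synthetic diamond
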