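# SYNTHETIC digitization stand-in for cumulative probabilities of reaching
# HD-ISS stage 3 (onset of functional decline), by age and CAG repeat length.
# Logistic curves: location 58/40/30 y and scale 7/6/5 y for CAG 40/45/50.
# The source staging-system curves are not published in reusable form; these
# values reproduce only their qualitative shape (sigmoidal, earlier onset at
# higher CAG) and must not be used for inference about real cohorts.
cag,age,cumulative_probability
40,20,0.004370
40,25,0.008887
40,30,0.017986
40,35,0.036065
40,40,0.071000
40,45,0.135036
40,50,0.241796
40,55,0.394468
40,60,0.570947
40,65,0.731059
40,70,0.847391
40,75,0.918980
40,80,0.958626
40,85,0.979309
40,90,0.989763
40,95,0.994962
45,20,0.034445
45,25,0.075858
45,30,0.158869
45,35,0.302941
45,40,0.500000
45,45,0.697059
45,50,0.841131
45,55,0.924142
45,60,0.965555
45,65,0.984733
45,70,0.993307
45,75,0.997080
45,80,0.998729
45,85,0.999447
45,90,0.999760
45,95,0.999896
50,20,0.119203
50,25,0.268941
50,30,0.500000
50,35,0.731059
50,40,0.880797
50,45,0.952574
50,50,0.982014
50,55,0.993307
50,60,0.997527
50,65,0.999089
50,70,0.999665
50,75,0.999877
50,80,0.999955
50,85,0.999983
50,90,0.999994
50,95,0.999998
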