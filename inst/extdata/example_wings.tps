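LM=19
320.707163 328.139743
403.296243 360.256214
472.685656 367.693588
539.381926 365.141375
608.933346 343.464210
658.956173 325.328901
630.722902 299.087139
575.984282 296.045311
545.768862 314.342991
499.514130 329.050842
469.133157 321.324610
435.546639 340.111420
404.001859 318.281294
505.784174 294.926467
550.810804 272.973915
488.440506 261.372539
436.895312 276.782218
390.837387 292.856162
353.192317 275.323736
IMAGE=AT1_A1_C1.jpg
ID=AT1_A1_C1_worker1
LM=19
354.250527 392.241992
443.396814 412.648262
508.941592 412.853016
576.175556 403.638278
641.849261 374.075965
692.760851 349.129987
656.338446 330.517878
610.922882 333.901476
573.700933 352.689720
534.985280 371.967762
500.956877 369.484650
469.528022 389.396337
439.815515 375.649477
530.970624 337.105503
576.049589 315.209122
511.700150 307.468722
459.801657 326.060183
418.333304 348.310387
378.639856 340.728071
IMAGE=AT1_A1_C1.jpg
ID=AT1_A1_C1_worker2
LM=19
404.355764 447.828461
475.215307 492.392604
540.176655 509.542481
601.479938 525.719977
665.462468 516.892241
716.201706 508.390164
696.244338 483.506944
649.233820 469.145507
613.535997 478.667272
570.785720 481.759562
542.678379 466.275167
509.448468 472.204253
484.866757 453.381648
579.700098 453.690876
627.375428 445.483916
570.510552 419.607326
516.687603 416.141636
469.457387 427.120488
442.571433 405.598947
IMAGE=AT1_A1_C2.jpg
ID=AT1_A1_C2_worker1
LM=19
398.641350 363.578663
459.313613 423.469829
519.095945 455.416336
579.728150 482.764568
637.395670 491.640836
693.909210 492.926443
679.191147 461.688734
638.460397 435.280214
595.809951 436.966506
553.126314 440.702622
524.856461 415.966629
491.038273 417.320009
472.164655 387.083437
572.825075 405.166524
616.658095 407.461670
566.662625 372.799923
521.205901 362.601147
472.608668 360.842709
443.623678 332.675652
IMAGE=AT1_A1_C2.jpg
ID=AT1_A1_C2_worker2
LM=19
331.480551 494.749318
417.878218 525.236824
484.669813 535.474185
545.436387 533.403021
611.975286 520.582213
662.301409 501.958620
632.257120 480.724595
585.142849 473.424997
545.180744 490.086075
510.894823 507.059769
471.963051 490.266002
449.149364 506.778733
406.654944 486.438523
505.999160 469.792738
549.563257 455.717476
487.681556 440.923172
437.441373 448.615931
391.592706 461.769599
360.001446 449.255883
IMAGE=CT1_A1_C1.jpg
ID=CT1_A1_C1_worker1
LM=19
266.274166 356.962020
340.549063 376.774593
397.981446 374.206036
459.207360 364.628807
508.689245 344.630490
552.129978 325.913515
524.434514 308.202819
483.383501 310.992908
450.498373 328.250372
422.137122 343.047126
390.461932 338.388273
364.170750 354.857806
335.159019 346.054338
417.233246 315.082631
450.124311 295.053486
394.355557 293.893993
352.856546 310.381929
314.689876 324.656732
277.613569 313.313825
IMAGE=CT1_A1_C1.jpg
ID=CT1_A1_C1_worker2
LM=19
366.828548 427.154093
434.999227 460.238841
497.320746 463.609137
561.563349 458.030438
613.108602 446.285091
657.878717 433.302773
630.123661 413.006078
587.534288 404.726098
554.438378 425.060136
518.389361 433.444424
489.761028 429.491212
461.848784 439.409072
431.393844 422.425230
518.537651 402.433587
560.546268 387.231600
505.494479 375.959797
456.447320 383.716147
414.734036 399.653239
385.090861 390.322077
IMAGE=CT1_A1_C2.jpg
ID=CT1_A1_C2_worker1
LM=19
333.773112 442.556371
408.879659 492.139952
473.143348 504.836157
539.821278 512.816538
605.149600 520.967206
651.929228 502.660832
624.117540 479.570715
581.563717 463.002109
540.619698 477.599843
501.338229 480.933957
471.492051 467.014169
437.927336 477.512826
409.452030 455.835952
505.845973 453.851598
552.347908 440.549786
494.407431 418.356894
441.935910 417.044164
397.436849 424.942800
365.314313 400.322248
IMAGE=CT1_A1_C2.jpg
ID=CT1_A1_C2_worker2
LM=19
372.622111 359.035777
458.997589 381.376091
524.551535 384.323556
595.856411 375.922549
656.701299 362.352170
698.816527 343.525801
666.635345 318.874944
619.750069 325.218107
580.003172 339.404789
549.705586 353.623552
513.826491 344.342775
483.354944 360.205205
452.036209 344.533175
543.847645 324.239498
586.625693 302.320664
520.239095 291.719843
466.538846 301.936374
422.786586 329.666197
396.955953 311.298208
IMAGE=MT1_A1_C1.jpg
ID=MT1_A1_C1_worker1
LM=19
305.382200 415.420942
378.274096 466.683252
440.169927 489.013877
505.386021 503.459634
563.770964 506.676396
612.618764 500.892892
587.215852 477.940473
543.702195 455.582824
505.527260 466.819433
471.361732 471.744701
437.856830 450.792331
408.091550 457.239908
384.025623 435.973143
473.742116 438.213653
516.937654 428.441710
463.485040 409.453530
408.927455 406.250687
369.624152 405.494980
338.474249 384.193090
IMAGE=MT1_A1_C1.jpg
ID=MT1_A1_C1_worker2
LM=19
388.694961 459.564753
476.875612 482.772949
544.115671 485.086921
610.272920 477.511154
675.132590 463.833718
719.381005 444.036588
682.446164 418.182861
634.002259 419.397709
603.657509 437.977280
566.395160 455.342673
527.540566 443.115992
500.775288 461.393379
469.326018 450.676623
556.807388 420.824101
599.672074 402.796234
533.415666 397.882312
480.109131 406.743627
445.983139 424.330684
403.369176 418.320910
IMAGE=MT1_A1_C2.jpg
ID=MT1_A1_C2_worker1
LM=19
301.684454 451.307406
369.233993 499.866117
431.727256 526.809412
484.649516 544.772956
548.900551 552.274814
593.288679 551.400781
574.484866 518.894122
527.993697 497.982374
497.214837 507.263717
456.646919 505.356445
429.543397 486.388216
399.947751 499.088182
370.123547 468.825765
462.882193 476.114499
507.767797 478.784531
450.105240 446.708328
398.309655 441.136984
362.420119 445.785231
330.814778 419.013103
IMAGE=MT1_A1_C2.jpg
ID=MT1_A1_C2_worker2
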