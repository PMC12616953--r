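wavelength_nm,value
622,3.35e-4
623,4.67e-4
624,6.44e-4
625,8.84e-4
626,0.001204
627,0.001628
628,0.002187
629,0.002918
630,0.003866
631,0.005086
632,0.006645
633,0.008622
634,0.011109
635,0.014215
636,0.018063
637,0.022794
638,0.028566
639,0.03555
640,0.043937
641,0.053926
642,0.065729
643,0.07956
644,0.095634
645,0.114162
646,0.135335
647,0.159326
648,0.18627
649,0.216265
650,0.249352
651,0.285512
652,0.324652
653,0.366604
654,0.411112
655,0.457833
656,0.506336
657,0.556101
658,0.606531
659,0.656956
660,0.706648
661,0.75484
662,0.800737
663,0.843548
664,0.882497
665,0.916855
666,0.945959
667,0.969233
668,0.986207
669,0.996534
670,1
671,0.991711
672,0.979739
673,0.9642
674,0.945284
675,0.923249
676,0.898409
677,0.871128
678,0.841807
679,0.81087
680,0.778752
681,0.745887
682,0.712699
683,0.679585
684,0.646913
685,0.615011
686,0.584163
687,0.554605
688,0.526525
689,0.500062
690,0.475308
691,0.452314
692,0.431088
693,0.411607
694,0.393817
695,0.377642
696,0.362986
697,0.349742
698,0.337795
699,0.327025
700,0.317313
701,0.308542
702,0.300601
703,0.293386
704,0.286801
705,0.280757
706,0.275177
707,0.269993
708,0.265143
709,0.260577
710,0.256249
711,0.252124
712,0.248168
713,0.244358
714,0.240671
715,0.237091
716,0.233603
717,0.230197
718,0.226863
719,0.223595
720,0.220387
721,0.217235
722,0.214135
723,0.211084
724,0.20808
725,0.205122
726,0.202208
727,0.199337
728,0.196507
729,0.193719
730,0.19097
731,0.18826
732,0.18559
733,0.182957
734,0.180362
735,0.177803
736,0.175281
737,0.172795
738,0.170344
739,0.167928
740,0.165546
741,0.163198
742,0.160883
743,0.158601
744,0.156351
745,0.154133
746,0.151947
747,0.149792
748,0.147667
749,0.145573
750,0.143508
751,0.141472
752,0.139466
753,0.137488
754,0.135537
755,0.133615
756,0.13172
757,0.129851
758,0.12801
759,0.126194
760,0.124404
761,0.122639
762,0.1209
763,0.119185
764,0.117494
765,0.115828
766,0.114185
767,0.112565
768,0.110969
769,0.109395
770,0.107843
771,0.106313
772,0.104805
773,0.103319
774,0.101853
775,0.100409
776,0.098984
777,0.09758
778,0.096196
779,0.094832
780,0.093487
781,0.092161
782,0.090853
783,0.089565
784,0.088294
785,0.087042
786,0.085807
787,0.08459
788,0.08339
789,0.082208
790,0.081042
791,0.079892
792,0.078759
793,0.077642
794,0.07654
795,0.075455
796,0.074384
797,0.073329
798,0.072289
799,0.071264
800,0.070253
801,0.069257
802,0.068274
803,0.067306
804,0.066351
805,0.06541
806,0.064482
807,0.063568
808,0.062666
809,0.061777
810,0.060901
811,0.060037
812,0.059185
813,0.058346
814,0.057518
815,0.056703
816,0.055898
817,0.055105
818,0.054324
819,0.053553
820,0.052794
821,0.052045
822,0.051307
823,0.050579
824,0.049861
825,0.049154
826,0.048457
827,0.04777
828,0.047092
829,0.046424
830,0.045766
831,0.045116
832,0.044477
833,0.043846
834,0.043224
835,0.042611
836,0.042006
837,0.04141
838,0.040823
839,0.040244
840,0.039673
841,0.03911
842,0.038556
843,0.038009
844,0.03747
845,0.036938
846,0.036414
847,0.035898
848,0.035389
849,0.034887
850,0.034392
851,0.033904
852,0.033423
853,0.032949
854,0.032482
855,0.032021
856,0.031567
857,0.031119
858,0.030678
859,0.030242
860,0.029814
861,0.029391
862,0.028974
863,0.028563
864,0.028158
865,0.027758
866,0.027365
867,0.026976
868,0.026594
869,0.026217
870,0.025845
871,0.025478
872,0.025117
873,0.02476
874,0.024409
875,0.024063
876,0.023722
877,0.023385
878,0.023054
879,0.022727
880,0.022404
881,0.022086
882,0.021773
883,0.021464
884,0.02116
885,0.02086
886,0.020564
887,0.020272
888,0.019985
889,0.019701
890,0.019422
891,0.019146
892,0.018875
893,0.018607
894,0.018343
895,0.018083
896,0.017826
897,0.017573
898,0.017324
899,0.017078
900,0.016836
901,0.016597
902,0.016362
903,0.01613
904,0.015901
905,0.015676
906,0.015453
907,0.015234
908,0.015018
909,0.014805
910,0.014595
911,0.014388
912,0.014184
913,0.013983
914,0.013784
915,0.013589
916,0.013396
917,0.013206
918,0.013019
919,0.012834
920,0.012652
921,0.012473
922,0.012296
923,0.012121
924,0.011949
925,0.01178
926,0.011613
927,0.011448
928,0.011286
929,0.011126
930,0.010968
931,0.010812
932,0.010659
933,0.010508
934,0.010359
935,0.010212
936,0.010067
937,0.009924
938,0.009783
939,0.009645
940,0.009508
941,0.009373
942,0.00924
943,0.009109
944,0.00898
945,0.008852
946,0.008727
947,0.008603
948,0.008481
949,0.008361
950,0.008242
951,0.008125
952,0.00801
953,0.007896
954,0.007784
955,0.007674
956,0.007565
957,0.007458
958,0.007352
959,0.007248
960,0.007145
961,0.007043
962,0.006944
963,0.006845
964,0.006748
965,0.006652
966,0.006558
967,0.006465
968,0.006373
969,0.006283
970,0.006194
971,0.006106
972,0.006019
973,0.005934
974,0.00585
975,0.005767
976,0.005685
977,0.005604
978,0.005525
979,0.005446
980,0.005369
981,0.005293
982,0.005218
983,0.005144
984,0.005071
985,0.004999
986,0.004928
987,0.004858
988,0.004789
989,0.004721
990,0.004654
991,0.004588
992,0.004523
993,0.004459
994,0.004396
995,0.004334
996,0.004272
997,0.004212
998,0.004152
999,0.004093
1000,0.004035
1001,0.003978
1002,0.003921
1003,0.003866
1004,0.003811
1005,0.003757
1006,0.003703
1007,0.003651
1008,0.003599
1009,0.003548
1010,0.003498
1011,0.003448
1012,0.003399
1013,0.003351
1014,0.003303
1015,0.003257
1016,0.00321
1017,0.003165
1018,0.00312
1019,0.003076
1020,0.003032
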