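wavelength_nm,value
613,0
614,0
615,0
616,0
617,0
618,0
619,0
620,0
621,0
622,0
623,0
624,0
625,0
626,0
627,0
628,0
629,0
630,0
631,0
632,0
633,0
634,0
635,0
636,0
637,0
638,0
639,0
640,0
641,0
642,0
643,0
644,0
645,0
646,0
647,1e-6
648,1e-6
649,1e-6
650,1e-6
651,1e-6
652,1e-6
653,1e-6
654,1e-6
655,1e-6
656,2e-6
657,2e-6
658,2e-6
659,2e-6
660,3e-6
661,3e-6
662,4e-6
663,4e-6
664,5e-6
665,6e-6
666,7e-6
667,8e-6
668,9e-6
669,1.1e-5
670,1.3e-5
671,1.6e-5
672,1.8e-5
673,2.2e-5
674,2.6e-5
675,3.1e-5
676,3.8e-5
677,4.5e-5
678,5.5e-5
679,6.7e-5
680,8.1e-5
681,1e-4
682,1.22e-4
683,1.51e-4
684,1.87e-4
685,2.33e-4
686,2.92e-4
687,3.68e-4
688,4.65e-4
689,5.92e-4
690,7.58e-4
691,9.76e-4
692,0.001265
693,0.00165
694,0.00217
695,0.002874
696,0.003836
697,0.005164
698,0.007011
699,0.009606
700,0.013284
701,0.018545
702,0.026137
703,0.037175
704,0.053311
705,0.076944
706,0.111412
707,0.161001
708,0.23036
709,0.322768
710,0.437041
711,0.564576
712,0.690066
713,0.797705
714,0.878495
715,0.932368
716,0.964891
717,0.982954
718,0.992271
719,0.996748
720,0.998744
721,0.999562
722,0.999865
723,0.999964
724,0.999992
725,0.999999
726,1
727,1
728,1
729,1
730,1
731,1
732,1
733,1
734,1
735,0.999999
736,0.999992
737,0.999964
738,0.999865
739,0.999562
740,0.998744
741,0.996748
742,0.992271
743,0.982954
744,0.964891
745,0.932368
746,0.878495
747,0.797705
748,0.690066
749,0.564576
750,0.437041
751,0.322768
752,0.23036
753,0.161001
754,0.111412
755,0.076944
756,0.053311
757,0.037175
758,0.026137
759,0.018545
760,0.013284
761,0.009606
762,0.007011
763,0.005164
764,0.003836
765,0.002874
766,0.00217
767,0.00165
768,0.001265
769,9.76e-4
770,7.58e-4
771,5.92e-4
772,4.65e-4
773,3.68e-4
774,2.92e-4
775,2.33e-4
776,1.87e-4
777,1.51e-4
778,1.22e-4
779,1e-4
780,8.1e-5
781,6.7e-5
782,5.5e-5
783,4.5e-5
784,3.8e-5
785,3.1e-5
786,2.6e-5
787,2.2e-5
788,1.8e-5
789,1.6e-5
790,1.3e-5
791,1.1e-5
792,9e-6
793,8e-6
794,7e-6
795,6e-6
796,5e-6
797,4e-6
798,4e-6
799,3e-6
800,3e-6
801,2e-6
802,2e-6
803,2e-6
804,2e-6
805,1e-6
806,1e-6
807,1e-6
808,1e-6
809,1e-6
810,1e-6
811,1e-6
812,1e-6
813,1e-6
814,0
815,0
816,0
817,0
818,0
819,0
820,0
821,0
822,0
823,0
824,0
825,0
826,0
827,0
828,0
829,0
830,0
831,0
832,0
833,0
834,0
835,0
836,0
837,0
838,0
839,0
840,0
841,0
842,0
843,0
844,0
845,0
846,0
847,0
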