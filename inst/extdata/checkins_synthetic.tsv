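bg01	2010-10-14T01:56:54Z	40.6	-104.9	L007
bg01	2010-10-14T02:35:55Z	40.3	-104.7	L004
bg01	2010-10-14T05:09:11Z	40.2	-104.8	L003
bg01	2010-10-14T17:39:26Z	40	-104.8	L008
bg01	2010-10-14T21:28:07Z	40.5	-105	L006
bg01	2010-10-14T21:29:50Z	40.6	-104.9	L007
bg01	2010-10-14T22:13:57Z	40.5	-105	L006
bg01	2010-10-14T23:12:45Z	40.2	-104.8	L003
bg01	2010-10-15T02:40:58Z	40.5	-105	L006
bg01	2010-10-15T05:48:26Z	40.3	-104.7	L004
bg01	2010-10-15T15:10:02Z	40.6	-104.9	L007
bg01	2010-10-15T21:57:32Z	40.4	-104.6	L005
bg01	2010-10-15T23:48:34Z	40	-104.8	L008
bg01	2010-10-16T00:17:22Z	40.6	-104.9	L007
bg01	2010-10-16T02:32:08Z	40.1	-104.9	L001
bg01	2010-10-16T05:17:05Z	40.2	-104.8	L003
bg01	2010-10-16T07:15:54Z	40.6	-104.9	L007
bg01	2010-10-16T08:47:00Z	40	-104.8	L008
bg01	2010-10-17T00:05:48Z	40.1	-104.9	L001
bg01	2010-10-17T02:30:58Z	40.4	-104.6	L005
c_ego01_01	2010-10-13T23:48:04Z	40.6	-104.9	P_c_ego01_01_02
c_ego01_01	2010-10-14T03:04:27Z	40.2	-104.8	L002
c_ego01_01	2010-10-14T07:53:31Z	40.3	-104.7	L003
c_ego01_01	2010-10-14T11:18:33Z	40.2	-104.6	P_c_ego01_01_08
c_ego01_01	2010-10-14T15:17:35Z	40	-104.6	P_c_ego01_01_22
c_ego01_01	2010-10-14T20:01:00Z	40.6	-104.7	P_c_ego01_01_18
c_ego01_01	2010-10-14T23:35:06Z	40.1	-104.7	P_c_ego01_01_07
c_ego01_01	2010-10-15T03:28:07Z	40	-104.8	P_c_ego01_01_06
c_ego01_01	2010-10-15T08:01:31Z	40.5	-105	L005
c_ego01_01	2010-10-15T12:34:24Z	40.3	-105	P_c_ego01_01_09
c_ego01_01	2010-10-15T16:09:15Z	40.5	-104.8	P_c_ego01_01_16
c_ego01_01	2010-10-15T19:31:05Z	40.2	-104.6	P_c_ego01_01_08
c_ego01_01	2010-10-15T23:07:06Z	40.4	-104.6	L004
c_ego01_01	2010-10-16T03:55:49Z	40.1	-105	P_c_ego01_01_25
c_ego01_01	2010-10-16T08:40:10Z	40.4	-104.9	P_c_ego01_01_10
c_ego01_01	2010-10-16T12:46:59Z	40.1	-104.9	L001
c_ego01_01	2010-10-16T15:57:44Z	40	-104.6	P_c_ego01_01_22
c_ego01_01	2010-10-16T19:59:51Z	40.2	-104.6	P_c_ego01_01_08
c_ego01_01	2010-10-16T23:54:10Z	40.6	-104.7	P_c_ego01_01_18
c_ego01_01	2010-10-17T04:29:36Z	40	-104.6	P_c_ego01_01_22
c_ego01_02	2010-10-13T23:40:39Z	40.1	-104.9	L001
c_ego01_02	2010-10-14T02:54:22Z	40.2	-104.8	L002
c_ego01_02	2010-10-14T07:30:30Z	40.4	-104.6	P_c_ego01_02_01
c_ego01_02	2010-10-14T11:34:46Z	40	-104.8	P_c_ego01_02_09
c_ego01_02	2010-10-14T15:12:51Z	40.4	-104.9	P_c_ego01_02_16
c_ego01_02	2010-10-14T19:53:22Z	40.1	-104.7	P_c_ego01_02_11
c_ego01_02	2010-10-14T23:34:06Z	40.3	-105	P_c_ego01_02_15
c_ego01_02	2010-10-15T03:25:26Z	40.6	-104.7	P_c_ego01_02_22
c_ego01_02	2010-10-15T07:48:28Z	40.5	-105	P_c_ego01_02_02
c_ego01_02	2010-10-15T12:32:45Z	40.3	-104.7	L003
c_ego01_02	2010-10-15T16:05:00Z	40.2	-104.8	L002
c_ego01_02	2010-10-15T19:30:36Z	40.5	-104.8	P_c_ego01_02_19
c_ego01_02	2010-10-15T22:57:59Z	40.6	-104.9	P_c_ego01_02_03
c_ego01_02	2010-10-16T03:57:24Z	40.3	-105	P_c_ego01_02_15
c_ego01_02	2010-10-16T08:15:21Z	40.4	-104.9	P_c_ego01_02_16
c_ego01_02	2010-10-16T12:54:03Z	40.1	-104.7	P_c_ego01_02_11
c_ego01_02	2010-10-16T15:40:05Z	40.1	-104.9	L001
c_ego01_02	2010-10-16T20:03:23Z	40.2	-104.6	P_c_ego01_02_12
c_ego01_02	2010-10-16T23:42:22Z	40.3	-105	P_c_ego01_02_15
c_ego01_02	2010-10-17T04:45:14Z	40	-104.6	P_c_ego01_02_25
ego01	2010-10-13T23:46:34Z	40.1	-104.9	L001
ego01	2010-10-14T03:07:23Z	40.2	-104.8	L002
ego01	2010-10-14T07:43:21Z	40.3	-104.7	L003
ego01	2010-10-14T11:24:12Z	40	-104.8	L007
ego01	2010-10-14T15:08:44Z	40	-104.8	L007
ego01	2010-10-14T19:54:22Z	40.6	-104.9	L006
ego01	2010-10-14T23:48:37Z	40.6	-104.9	L006
ego01	2010-10-15T03:36:33Z	40	-104.8	L007
ego01	2010-10-15T07:55:39Z	40.5	-105	L005
ego01	2010-10-15T12:38:21Z	40.3	-104.7	L003
ego01	2010-10-15T16:09:21Z	40.2	-104.8	L002
ego01	2010-10-15T19:40:35Z	40.5	-105	L005
ego01	2010-10-15T23:08:06Z	40.4	-104.6	L004
ego01	2010-10-16T03:46:21Z	40.1	-104.7	L008
ego01	2010-10-16T08:28:13Z	40.6	-104.9	L006
ego01	2010-10-16T12:54:15Z	40.1	-104.9	L001
ego01	2010-10-16T15:44:10Z	40.1	-104.9	L001
ego01	2010-10-16T20:02:45Z	40	-104.8	L007
ego01	2010-10-16T23:51:08Z	40.2	-104.8	L002
ego01	2010-10-17T04:44:28Z	40.2	-104.8	L002
s_ego01_01	2010-10-13T23:48:04Z	40.1	-104.9	L001
s_ego01_01	2010-10-14T02:56:18Z	40.2	-104.8	L002
s_ego01_01	2010-10-14T07:31:30Z	40.3	-105	P_s_ego01_01_04
s_ego01_01	2010-10-14T11:29:30Z	40.6	-104.9	L007
s_ego01_01	2010-10-14T15:14:48Z	40.6	-104.7	P_s_ego01_01_19
s_ego01_01	2010-10-14T20:08:30Z	40.5	-105	L006
s_ego01_01	2010-10-14T23:57:57Z	40.2	-104.6	P_s_ego01_01_03
s_ego01_01	2010-10-15T03:46:57Z	40.1	-105	P_s_ego01_01_25
s_ego01_01	2010-10-15T07:55:17Z	40.4	-104.9	P_s_ego01_01_14
s_ego01_01	2010-10-15T12:23:56Z	40.3	-104.7	L003
s_ego01_01	2010-10-15T15:58:42Z	40.2	-104.8	L002
s_ego01_01	2010-10-15T19:55:05Z	40.5	-104.8	P_s_ego01_01_17
s_ego01_01	2010-10-15T23:14:00Z	40.4	-104.6	L004
s_ego01_01	2010-10-16T03:31:30Z	40	-104.8	L008
s_ego01_01	2010-10-16T08:16:26Z	40.5	-105	L006
s_ego01_01	2010-10-16T13:03:48Z	40.1	-104.9	L001
s_ego01_01	2010-10-16T15:49:49Z	40.1	-104.9	L001
s_ego01_01	2010-10-16T19:58:44Z	40.5	-104.8	P_s_ego01_01_17
s_ego01_01	2010-10-16T23:57:28Z	40	-104.6	P_s_ego01_01_20
s_ego01_01	2010-10-17T04:37:16Z	40.1	-104.7	P_s_ego01_01_01
s_ego01_02	2010-10-13T23:38:52Z	40.4	-104.9	P_s_ego01_02_12
s_ego01_02	2010-10-14T03:15:06Z	40.2	-104.8	L002
s_ego01_02	2010-10-14T07:55:05Z	40.1	-105	P_s_ego01_02_24
s_ego01_02	2010-10-14T11:26:33Z	40.4	-104.6	L007
s_ego01_02	2010-10-14T15:11:17Z	40.2	-104.9	P_s_ego01_02_25
s_ego01_02	2010-10-14T19:47:41Z	40	-104.8	P_s_ego01_02_06
s_ego01_02	2010-10-14T23:43:41Z	40.3	-105	P_s_ego01_02_09
s_ego01_02	2010-10-15T03:28:18Z	40.4	-104.6	L007
s_ego01_02	2010-10-15T07:56:41Z	40.6	-104.7	P_s_ego01_02_18
s_ego01_02	2010-10-15T12:42:29Z	40	-104.6	P_s_ego01_02_21
s_ego01_02	2010-10-15T16:15:48Z	40.2	-104.6	P_s_ego01_02_08
s_ego01_02	2010-10-15T19:34:08Z	40.3	-104.7	L005
s_ego01_02	2010-10-15T23:02:37Z	40.5	-104.8	P_s_ego01_02_17
s_ego01_02	2010-10-16T03:42:47Z	40.5	-105	L008
s_ego01_02	2010-10-16T08:37:39Z	40.6	-104.9	P_s_ego01_02_02
s_ego01_02	2010-10-16T12:52:33Z	40.1	-104.7	P_s_ego01_02_07
s_ego01_02	2010-10-16T15:37:23Z	40.1	-104.9	L001
s_ego01_02	2010-10-16T20:06:46Z	40.6	-104.7	P_s_ego01_02_18
s_ego01_02	2010-10-17T00:05:37Z	40.2	-104.8	L002
s_ego01_02	2010-10-17T04:31:01Z	40.2	-104.8	L002
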